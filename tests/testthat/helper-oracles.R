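# Independent oracles, deliberately written without any of the package's
# numerical machinery: naive direct summation of the conditional likelihood
# (no log-sum-exp; safe for the small counts it is used with) and grid
# maximisation. They check the Newton fit, never stand in for it.

oracle_loglik <- function(beta, a, n1, b, n2) {
  total <- 0
  for (i in seq_along(a)) {
    t <- a[i] + b[i]
    if (t == 0 || t == n1[i] + n2[i]) next
    u <- max(0, t - n2[i]):min(n1[i], t)
    num <- choose(n1[i], a[i]) * choose(n2[i], b[i]) * exp(beta * a[i])
    den <- sum(choose(n1[i], u) * choose(n2[i], t - u) * exp(beta * u))
    total <- total + log(num / den)
  }
  total
}

# Argmax of the conditional likelihood by grid search over [-10, 10]:
# coarse pass at step 0.01, then a fine pass at step 1e-4 around the
# coarse optimum (exact for this log-concave likelihood).
oracle_grid_beta <- function(strata) {
  a <- strata$index_events; n1 <- strata$index_trials
  b <- strata$comparison_events; n2 <- strata$comparison_trials
  ll <- function(betas) vapply(betas, oracle_loglik, 0, a, n1, b, n2)
  coarse <- seq(-10, 10, by = 0.01)
  b0 <- coarse[which.max(ll(coarse))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(ll(fine))]
}

# The two hypothetical family units of the worked concordance example,
# encoded as a row-per-individual table with pre-coded variant flags.
table1_df <- function() {
  flag_row <- function(family_id, member_id, role, profile) {
    flags <- as.integer(c("classical", "a1_asymmetry", "incomplete_pcom",
                          "fetal_pc") %in% profile)
    data.frame(family_id = family_id, member_id = member_id, role = role,
               classical = flags[1], a1_asymmetry = flags[2],
               incomplete_pcom = flags[3], fetal_pc = flags[4])
  }
  rbind(
    flag_row("index", "proband", "proband",
             c("incomplete_pcom", "a1_asymmetry")),
    flag_row("index", "brother", "fdr", "classical"),
    flag_row("index", "daughter1", "fdr", "incomplete_pcom"),
    flag_row("index", "son1", "fdr", c("incomplete_pcom", "a1_asymmetry")),
    flag_row("index", "son2", "fdr", "fetal_pc"),
    flag_row("index", "daughter2", "fdr", "incomplete_pcom"),
    flag_row("comparison", "proband", "proband", "classical"),
    flag_row("comparison", "brother1", "fdr", c("a1_asymmetry", "fetal_pc")),
    flag_row("comparison", "brother2", "fdr", "classical"),
    flag_row("comparison", "brother3", "fdr", "incomplete_pcom"),
    flag_row("comparison", "sister", "fdr", "classical"))
}

member_profiles <- function(fam) lapply(fam$fdrs, `[[`, "profile")

# Random valid diameter set for classification fuzzing.
random_diameters <- function() {
  d <- stats::runif(6, 0, 3)
  names(d) <- c("a1_left", "a1_right", "p1_left", "p1_right",
                "pcom_left", "pcom_right")
  if (d["a1_left"] == 0 && d["a1_right"] == 0) d["a1_left"] <- 1
  d
}
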