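#' Read a family cohort from a row-per-individual table
#'
#' Builds the family-structured cohort the concordance analysis operates on.
#' Each row is one imaged individual; `family_id` groups rows into family
#' units and `role` designates exactly one proband per family. Variant
#' profiles come either from the four pre-coded 0/1 columns (`classical`,
#' `a1_asymmetry`, `incomplete_pcom`, `fetal_pc`) or are derived from the
#' six diameter columns via [classify_cow()]. When both are present the
#' derived profile must equal the pre-coded one, which guards against stale
#' codings.
#'
#' @param data Data frame with columns `family_id`, `member_id`, `role`
#'   (`"proband"`/`"fdr"`), and either the six diameter columns
#'   (`a1_left`, `a1_right`, `p1_left`, `p1_right`, `pcom_left`,
#'   `pcom_right`) or the four variant flag columns, or both. Optional:
#'   `sex`, `modality` (`"MRA"`/`"CTA"`/`"DSA"`), `slice_thickness_mm`,
#'   `quality_ok`. Alternatively a path to a CSV file with that schema.
#' @param group_label Label for the study group (e.g. `"group1"`).
#' @param rules [cow_rules()] used when classifying from diameters.
#' @param col_map Optional named character vector mapping the schema names
#'   above to the column names actually present, e.g.
#'   `c(family_id = "FamID", a1_left = "A1_L")`.
#' @return An object of class `cow_cohort`: a list with `group_label` and
#'   `families`, each family holding a `proband` record and a list of
#'   `fdrs` records.
#' @export
read_cohort <- function(data, group_label = "cohort", rules = cow_rules(),
                        col_map = NULL) {
  if (is.character(data) && length(data) == 1L)
    data <- utils::read.csv(data, stringsAsFactors = FALSE)
  data <- as.data.frame(data)
  if (!is.null(col_map)) {
    hit <- match(col_map, names(data))
    if (anyNA(hit))
      stop("col_map names column(s) not in the data: ",
           paste(col_map[is.na(hit)], collapse = ", "), call. = FALSE)
    names(data)[hit] <- names(col_map)
  }
  for (col in c("family_id", "member_id", "role"))
    if (is.null(data[[col]]))
      stop("mandatory column missing: ", col, call. = FALSE)
  if (!all(data$role %in% c("proband", "fdr")))
    stop("role must be 'proband' or 'fdr'", call. = FALSE)
  key <- paste(data$family_id, data$member_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (family_id, member_id): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])),
               collapse = ", "), call. = FALSE)

  have_diam <- all(DIAMETER_COLS %in% names(data))
  have_flags <- all(names(COW_VARIANTS) %in% names(data))
  if (!have_diam && !have_flags)
    stop("need the six diameter columns and/or the four variant flag ",
         "columns", call. = FALSE)

  mk_individual <- function(row) {
    diam <- if (have_diam) {
      d <- as.numeric(row[1, DIAMETER_COLS])
      names(d) <- DIAMETER_COLS
      if (all(is.na(d))) NULL else d
    } else NULL
    profile <- NULL
    if (have_flags) {
      flags <- as.numeric(row[1, names(COW_VARIANTS)])
      if (anyNA(flags) || !all(flags %in% c(0, 1)))
        stop("variant flags must be 0/1 (member ", row$member_id[1], " of ",
             "family ", row$family_id[1], ")", call. = FALSE)
      profile <- names(COW_VARIANTS)[flags == 1]
    }
    if (!is.null(diam) && !anyNA(diam)) {
      derived <- classify_cow(diam, rules)
      if (!is.null(profile)) {
        if (!setequal(derived, profile))
          stop("pre-coded profile disagrees with classification for member ",
               row$member_id[1], " of family ", row$family_id[1],
               ": coded {", paste(profile, collapse = ","), "} vs derived {",
               paste(derived, collapse = ","), "}", call. = FALSE)
      } else profile <- derived
    }
    if (is.null(profile))
      stop("no usable profile for member ", row$member_id[1], " of family ",
           row$family_id[1], " (diameters incomplete, no variant flags)",
           call. = FALSE)
    profile_to_mask(profile)  # validates invariants
    list(member_id = as.character(row$member_id[1]),
         role = row$role[1],
         diameters = diam,
         profile = profile,
         sex = if (!is.null(row$sex)) row$sex[1] else NA,
         modality = if (!is.null(row$modality)) row$modality[1] else NA,
         slice_thickness_mm = if (!is.null(row$slice_thickness_mm))
           as.numeric(row$slice_thickness_mm[1]) else NA_real_,
         quality_ok = if (!is.null(row$quality_ok))
           as.logical(row$quality_ok[1]) else NA)
  }

  fams <- split(data, factor(data$family_id, levels = unique(data$family_id)))
  families <- lapply(names(fams), function(fid) {
    fd <- fams[[fid]]
    members <- lapply(seq_len(nrow(fd)), function(i) mk_individual(fd[i, ]))
    is_pro <- vapply(members, function(m) m$role == "proband", TRUE)
    if (sum(is_pro) != 1L)
      stop("family ", fid, " has ", sum(is_pro),
           " probands (exactly one required)", call. = FALSE)
    structure(list(family_id = fid,
                   proband = members[[which(is_pro)]],
                   fdrs = members[!is_pro]),
              class = "cow_family")
  })
  names(families) <- names(fams)
  structure(list(group_label = group_label, families = families),
            class = "cow_cohort")
}

#' @export
print.cow_cohort <- function(x, ...) {
  nf <- length(x$families)
  nfdr <- sum(vapply(x$families, function(f) length(f$fdrs), 1L))
  cat("cow_cohort '", x$group_label, "': ", nf, " families, ",
      nfdr, " FDRs\n", sep = "")
  invisible(x)
}

#' Flatten a cohort back to a row-per-individual data frame
#'
#' Inverse of [read_cohort()]: a round trip through
#' `read_cohort(as.data.frame(cohort))` reproduces the cohort.
#'
#' @param x A `cow_cohort`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @export
as.data.frame.cow_cohort <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- lapply(x$families, function(fam) {
    members <- c(list(fam$proband), fam$fdrs)
    do.call(rbind, lapply(members, function(m) {
      d <- if (is.null(m$diameters))
        stats::setNames(rep(NA_real_, 6L), DIAMETER_COLS) else m$diameters
      flags <- as.integer(names(COW_VARIANTS) %in% m$profile)
      names(flags) <- names(COW_VARIANTS)
      cbind(data.frame(family_id = fam$family_id, member_id = m$member_id,
                       role = m$role, stringsAsFactors = FALSE),
            as.data.frame(as.list(d)), as.data.frame(as.list(flags)),
            data.frame(sex = m$sex, modality = m$modality,
                       slice_thickness_mm = m$slice_thickness_mm,
                       quality_ok = m$quality_ok))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the imaging-based exclusion filters
#'
#' Drops individuals imaged by digital subtraction angiography only, by CTA
#' with slice thickness above 1 mm, or flagged as poor quality; then drops
#' families left without a valid unit (proband excluded, or no imaged FDR
#' remaining). Filtering never fails; every removal is logged.
#'
#' @param cohort A `cow_cohort`.
#' @param max_cta_slice_mm CTA slice-thickness cut-off in mm (default 1.0).
#' @return A list with `cohort` (the filtered `cow_cohort`) and `log`, a
#'   data frame of `family_id`, `member_id`, `reason` rows, one per
#'   excluded individual.
#' @export
apply_exclusions <- function(cohort, max_cta_slice_mm = 1.0) {
  stopifnot(inherits(cohort, "cow_cohort"))
  log <- list()
  note <- function(fid, mid, reason)
    log[[length(log) + 1L]] <<- data.frame(family_id = fid, member_id = mid,
                                           reason = reason)
  excl_reason <- function(m) {
    if (!is.na(m$modality) && m$modality == "DSA") return("DSA only")
    if (!is.na(m$modality) && m$modality == "CTA" &&
        !is.na(m$slice_thickness_mm) &&
        m$slice_thickness_mm > max_cta_slice_mm)
      return(sprintf("CTA slice >%gmm", max_cta_slice_mm))
    if (!is.na(m$quality_ok) && !m$quality_ok) return("poor quality imaging")
    NA_character_
  }
  families <- list()
  for (fam in cohort$families) {
    pro_reason <- excl_reason(fam$proband)
    keep <- list()
    for (m in fam$fdrs) {
      r <- excl_reason(m)
      if (is.na(r)) keep[[length(keep) + 1L]] <- m
      else note(fam$family_id, m$member_id, r)
    }
    if (!is.na(pro_reason)) {
      note(fam$family_id, fam$proband$member_id, pro_reason)
      for (m in keep)
        note(fam$family_id, m$member_id, "family dropped: proband excluded")
    } else if (!length(keep)) {
      note(fam$family_id, fam$proband$member_id,
           "family dropped: no FDR remaining")
    } else {
      fam$fdrs <- keep
      families[[fam$family_id]] <- fam
    }
  }
  cohort$families <- families
  log <- if (length(log)) do.call(rbind, log)
  else data.frame(family_id = character(), member_id = character(),
                  reason = character())
  rownames(log) <- NULL
  list(cohort = cohort, log = log)
}

#' Write an analysis result table to CSV
#'
#' One row per outcome. Numeric values are written with 17 significant
#' digits so that reading the file back reproduces them exactly.
#'
#' @param result A `cow_aggregate` (from [run_resampling()]), a
#'   `cow_meta_table` (from [run_full_study()]), or any data frame.
#' @param destination File path.
#' @param provenance Optional named list written as `# key: value` comment
#'   header lines (seed, configuration, version).
#' @return `destination`, invisibly.
#' @export
write_results <- function(result, destination, provenance = NULL) {
  df <- as.data.frame(result)
  out <- df
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- "NA"
    trimws(s)
  })
  con <- file(destination, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, function(v)
                         paste(format(v), collapse = " "), "")), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(destination)
}

#' Read back a result table written by [write_results()]
#'
#' @param path File path.
#' @return A data frame; provenance header lines are attached as the
#'   `"provenance"` attribute.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  df <- utils::read.csv(text = lines[!hdr], stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^# ", "", lines[hdr])
  df
}
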