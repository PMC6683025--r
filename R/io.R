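# Reading, validating and harmonizing per-SNP two-sample summary statistics.
#
# The canonical tabular layout is one row per (exposure, SNP) pair with both
# the SNP-exposure and SNP-outcome associations. p-values are carried as the
# printed text plus a derived log10 column because exposure GWAS p-values can
# be far below the double-precision floor (~1e-308).

#' Standard column set of an association table
#'
#' The thirteen columns every association table carries, in the order they
#' appear in the tab-separated dialect, before the derived columns
#' (`log10_p_exp`, `log10_p_out`, `var_exp_lo`, `var_exp_hi`) are appended.
#'
#' @return Character vector of column names.
#' @export
assoc_columns <- function() {
  c("exposure", "rsid", "gene", "chr", "ea", "nea",
    "beta_exp", "se_exp", "p_exp", "beta_out", "se_out", "p_out",
    "var_explained_pct")
}

valid_alleles <- c("A", "C", "G", "T")

# Normalise unicode dashes/multiplication signs so "3.3 × 10^-971" and
# en-dash ranges parse like their ASCII forms.
normalize_numeric_text <- function(x) {
  x <- gsub("−|–|—", "-", x)
  x <- gsub("\\s*×\\s*10\\^?", "e", x)
  x <- gsub("\\^", "", x)
  trimws(x)
}

#' Parse p-value text to log10
#'
#' Accepts plain decimals (`"0.158"`), scientific notation (`"3.5e-64"`),
#' and typeset forms (`"3.3 × 10^-971"`). Values below the double floor
#' are handled exactly on the log10 scale.
#'
#' @param x Character vector of p-value strings.
#' @return Numeric vector, log10 of the p-values (`NA` where unparseable).
#' @export
parse_p_log10 <- function(x) {
  x <- normalize_numeric_text(x)
  out <- rep(NA_real_, length(x))
  sci <- grepl("^[0-9.]+[eE][-+]?[0-9]+$", x)
  if (any(sci)) {
    mant <- as.numeric(sub("[eE].*$", "", x[sci]))
    expo <- as.numeric(sub("^.*[eE]", "", x[sci]))
    out[sci] <- log10(mant) + expo
  }
  plain <- !sci & grepl("^[0-9.]+$", x)
  out[plain] <- log10(as.numeric(x[plain]))
  out
}

# Format a two-sided normal p-value from |z| as text + log10, robust to
# underflow (used by the simulator so its tables share the fixture's dialect).
p_text_from_z <- function(z) {
  log_p <- pnorm(-abs(z), log.p = TRUE) + log(2)
  log10_p <- log_p / log(10)
  txt <- ifelse(
    log10_p > -4,
    sprintf("%.3g", pmin(1, exp(log_p))),
    sprintf("%.2fe%.0f", 10^(log10_p - floor(log10_p)), floor(log10_p))
  )
  list(text = txt, log10 = pmin(0, log10_p))
}

parse_var_range <- function(x) {
  x <- normalize_numeric_text(x)
  parts <- strsplit(x, "-", fixed = TRUE)
  lo <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), numeric(1))
  hi <- vapply(parts, function(p) {
    suppressWarnings(as.numeric(p[min(2L, length(p))]))
  }, numeric(1))
  tibble::tibble(lo = lo, hi = hi)
}

# Append derived columns (log10 p, variance-explained interval) to a table
# that carries the thirteen dialect columns.
derive_assoc_columns <- function(tbl) {
  rng <- parse_var_range(tbl$var_explained_pct)
  dplyr::mutate(
    tbl,
    log10_p_exp = parse_p_log10(.data$p_exp),
    log10_p_out = parse_p_log10(.data$p_out),
    var_exp_lo = rng$lo,
    var_exp_hi = rng$hi
  )
}

#' Validate an association table
#'
#' Checks the structural invariants of a two-sample summary-statistic table:
#' required columns, chromosome in 1-22, A/C/G/T alleles with effect and
#' non-effect distinct, finite betas, positive standard errors, parseable
#' p-values in (0, 1], non-negative ordered variance-explained intervals,
#' and no duplicated (exposure, rsid) pair. Failures are reported with the
#' offending row index.
#'
#' @param tbl A tibble with the columns of [assoc_columns()] (derived columns
#'   are recomputed if absent).
#' @return The validated tibble, invisibly augmented with derived columns.
#' @export
validate_association_table <- function(tbl) {
  missing_cols <- setdiff(assoc_columns(), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("log10_p_exp", "log10_p_out", "var_exp_lo", "var_exp_hi") %in% names(tbl))) {
    tbl <- derive_assoc_columns(tbl)
  }
  fail <- function(rows, what) {
    if (length(rows) > 0) {
      abort(sprintf("validation error: %s (row %s)", what,
                    paste(rows, collapse = ", ")))
    }
  }
  n <- nrow(tbl)
  if (n == 0) return(invisible(tbl))
  idx <- seq_len(n)

  for (fld in c("beta_exp", "se_exp", "beta_out", "se_out")) {
    bad <- idx[!is.finite(tbl[[fld]])]
    fail(bad, paste0("non-numeric or missing ", fld))
  }
  fail(idx[tbl$se_exp <= 0], "se_exp must be > 0")
  fail(idx[tbl$se_out <= 0], "se_out must be > 0")
  fail(idx[!(tbl$chr %in% 1:22)], "chr must be an integer in 1-22")
  fail(idx[!(tbl$ea %in% valid_alleles)], "ea must be one of A/C/G/T")
  fail(idx[!(tbl$nea %in% valid_alleles)], "nea must be one of A/C/G/T")
  fail(idx[tbl$ea == tbl$nea], "ea and nea must differ")
  fail(idx[!is.finite(tbl$log10_p_exp) | tbl$log10_p_exp > 0],
       "p_exp must be a p-value in (0, 1]")
  fail(idx[!is.finite(tbl$log10_p_out) | tbl$log10_p_out > 0],
       "p_out must be a p-value in (0, 1]")
  fail(idx[!is.finite(tbl$var_exp_lo) | !is.finite(tbl$var_exp_hi) |
             tbl$var_exp_lo < 0 | tbl$var_exp_hi < tbl$var_exp_lo],
       "var_explained_pct must be a non-negative value or lo-hi range")
  dup <- duplicated(paste(tbl$exposure, tbl$rsid, sep = "\r"))
  fail(idx[dup], "duplicated (exposure, rsid) pair")
  invisible(tbl)
}

#' Read an association table from tab-separated text
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param dialect Optional column-name map adapting a foreign header: a named
#'   character vector or list `c(standard = "foreign", ...)`, or the path to a
#'   YAML file containing such a map. Standard names are those of
#'   [assoc_columns()].
#' @return A validated tibble with the standard and derived columns.
#' @export
read_association_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(dialect)) {
    if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
      dialect <- yaml::read_yaml(dialect)
    }
    dialect <- unlist(dialect)
    known <- intersect(names(dialect), assoc_columns())
    for (std in known) {
      if (!dialect[[std]] %in% names(raw)) {
        abort(paste0("schema error: mapped column not in header: ", dialect[[std]]))
      }
    }
    names(raw)[match(dialect[known], names(raw))] <- known
  }
  missing_cols <- setdiff(assoc_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[assoc_columns()]

  num_field <- function(x, fld) {
    v <- suppressWarnings(as.numeric(normalize_numeric_text(x)))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("parse error: non-numeric %s (row %s)", fld,
                    paste(bad, collapse = ", ")))
    }
    v
  }
  tbl <- dplyr::mutate(
    tibble::as_tibble(raw),
    chr = as.integer(num_field(.data$chr, "chr")),
    beta_exp = num_field(.data$beta_exp, "beta_exp"),
    se_exp = num_field(.data$se_exp, "se_exp"),
    beta_out = num_field(.data$beta_out, "beta_out"),
    se_out = num_field(.data$se_out, "se_out")
  )
  tbl <- derive_assoc_columns(tbl)
  validate_association_table(tbl)
  tbl
}

#' Write an association table as tab-separated text
#'
#' Writes the thirteen standard columns (derived columns are dropped); a table
#' written and re-read round-trips identically.
#'
#' @param tbl An association table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tbl, path) {
  readr::write_tsv(tbl[assoc_columns()], path, progress = FALSE)
  invisible(path)
}

#' Align rows to a target effect allele
#'
#' Re-expresses selected rows of an association table on a chosen effect
#' allele: rows already reported on the target allele are untouched; rows
#' reported on the opposite allele have their alleles swapped and both betas
#' negated (standard errors and p-values are orientation-invariant). Applying
#' the same harmonization twice restores the input. No strand inference is
#' attempted: a target allele that is neither of a row's alleles is an error.
#'
#' @param tbl An association table.
#' @param target The target effect allele(s): a single allele (applied to
#'   every row), a named character vector `c(rsid = allele, ...)` (applied to
#'   matching rsids), or a data frame with columns `rsid` and `ea`.
#' @return The table with the selected rows re-oriented.
#' @export
harmonize_alleles <- function(tbl, target) {
  if (is.data.frame(target)) {
    target <- setNames(target$ea, target$rsid)
  }
  if (is.null(names(target))) {
    if (length(target) != 1) {
      abort("unnamed `target` must be a single allele")
    }
    want <- rep(target, nrow(tbl))
  } else {
    want <- unname(target[tbl$rsid])
  }
  touch <- !is.na(want)
  mism <- which(touch & want != tbl$ea & want != tbl$nea)
  if (length(mism) > 0) {
    abort(sprintf(
      "allele mismatch: target allele is neither EA nor NEA (row %s)",
      paste(mism, collapse = ", ")))
  }
  flip <- touch & want == tbl$nea
  if (any(flip)) {
    old_ea <- tbl$ea[flip]
    tbl$ea[flip] <- tbl$nea[flip]
    tbl$nea[flip] <- old_ea
    tbl$beta_exp[flip] <- -tbl$beta_exp[flip]
    tbl$beta_out[flip] <- -tbl$beta_out[flip]
  }
  tbl
}

#' Check printed p-values against printed beta/SE ratios
#'
#' A diagnostic for rounded published tables: the |z| implied by each printed
#' p-value (two-sided normal) is compared with the printed |beta|/SE. Because
#' published betas and SEs are rounded to few digits, agreement is assessed as
#' a ratio band rather than an equality.
#'
#' @param tbl An association table.
#' @param band Acceptable range for `z_from_p / (|beta|/se)`.
#' @return A tibble with per-row implied ratios and a `consistent` flag for
#'   both the exposure and outcome associations.
#' @export
check_p_consistency <- function(tbl, band = c(0.5, 2)) {
  z_from_log10 <- function(l10) {
    -qnorm(l10 * log(10) + log(0.5), log.p = TRUE)
  }
  ratio <- function(l10, beta, se) {
    z_p <- z_from_log10(l10)
    z_bs <- abs(beta) / se
    ifelse(z_bs == 0 & z_p < 0.2, 1, z_p / z_bs)
  }
  r_exp <- ratio(tbl$log10_p_exp, tbl$beta_exp, tbl$se_exp)
  r_out <- ratio(tbl$log10_p_out, tbl$beta_out, tbl$se_out)
  tibble::tibble(
    exposure = tbl$exposure,
    rsid = tbl$rsid,
    ratio_exp = r_exp,
    ratio_out = r_out,
    consistent = r_exp >= band[1] & r_exp <= band[2] &
      r_out >= band[1] & r_out <= band[2]
  )
}
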