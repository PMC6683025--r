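# Bundled instrument set: 22 (fatty acid, SNP) association rows covering ten
# plasma phospholipid fatty acids and an atrial fibrillation GWAS of 65,446
# cases / 522,744 non-cases, plus the per-fatty-acid SD scale factors (% of
# total plasma fatty acids per 1 SD) used to express causal effects per SD.
#
# Exposure betas are % total plasma fatty acids per effect-allele copy;
# outcome betas are log odds ratios of atrial fibrillation per copy.

#' Bundled fatty acid / atrial fibrillation association table
#'
#' The curated two-sample summary-statistic table behind the worked analyses:
#' 22 rows, 16 distinct SNPs, 10 fatty acids. SNPs shared across fatty acids
#' (e.g. rs174547) appear once per fatty acid, in the orientation their
#' exposure GWAS reported, so the same SNP can occur on opposite effect
#' alleles for different exposures; see [harmonize_alleles()].
#'
#' @return A validated association tibble (see [assoc_columns()]).
#' @export
#' @examples
#' tbl <- fa_af_associations()
#' dplyr::count(tbl, exposure)
fa_af_associations <- function() {
  tbl <- tibble::tribble(
    ~exposure, ~rsid, ~gene, ~chr, ~ea, ~nea, ~var_explained_pct,
    ~beta_exp, ~se_exp, ~p_exp, ~beta_out, ~se_out, ~p_out,
    "alpha-linolenic acid",   "rs174547",   "FADS1",      11L, "C", "T", "1.0",      0.02, 0.001, "3.5e-64",  -0.011, 0.008, "0.158",
    "eicosapentaenoic acid",  "rs3798713",  "ELOVL2",      6L, "C", "G", "0.4",      0.04, 0.005, "1.9e-12",   0.002, 0.008, "0.797",
    "eicosapentaenoic acid",  "rs174538",   "C11orf10",   11L, "G", "A", "1.7",      0.08, 0.005, "5.4e-58",   0.014, 0.008, "0.073",
    "docosapentaenoic acid",  "rs780094",   "GCKR",        2L, "T", "C", "0.5",      0.02, 0.003, "9.0e-9",   -0.008, 0.007, "0.295",
    "docosapentaenoic acid",  "rs3734398",  "ELOVL2",      6L, "C", "T", "2.7",      0.04, 0.003, "9.7e-43",  -0.002, 0.007, "0.798",
    "docosapentaenoic acid",  "rs174547",   "FADS1",      11L, "T", "C", "8.4",      0.08, 0.003, "3.8e-154",  0.011, 0.008, "0.158",
    "docosahexaenoic acid",   "rs2236212",  "ELOVL2",      6L, "G", "C", "0.7",      0.11, 0.014, "1.3e-15",  -0.002, 0.007, "0.816",
    "linoleic acid",          "rs10740118", "JMJD1C",     10L, "G", "C", "0.2-0.7",  0.25, 0.050, "8.1e-9",   -0.047, 0.007, "4.9e-11",
    "linoleic acid",          "rs174547",   "FADS1",      11L, "C", "T", "7.6-18.1", 1.47, 0.050, "5.0e-274", -0.011, 0.008, "0.158",
    "linoleic acid",          "rs16966952", "NTAN1",      16L, "G", "A", "0.5-2.5",  0.35, 0.040, "1.2e-15",  -0.004, 0.008, "0.583",
    "arachidonic acid",       "rs174547",   "FADS1",      11L, "T", "C", "3.7-37.6", 1.69, 0.020, "3.3e-971",  0.011, 0.008, "0.158",
    "arachidonic acid",       "rs16966952", "NTAN1",      16L, "G", "A", "0.1-0.6",  0.20, 0.030, "2.4e-10",  -0.004, 0.008, "0.583",
    "palmitoleic acid",       "rs780093",   "GCKR",        2L, "T", "C", "0.2-0.9",  0.02, 0.003, "9.8e-10",  -0.007, 0.007, "0.312",
    "palmitoleic acid",       "rs6722456",  "RN7SKP93",    2L, "G", "A", "0.01-0.6", 0.05, 0.009, "4.1e-8",    0.006, 0.020, "0.765",
    "palmitoleic acid",       "rs603424",   "SCD/PKD2L1", 10L, "G", "A", "0.3-1.6",  0.03, 0.004, "5.7e-15",   0.038, 0.010, "8.5e-5",
    "palmitoleic acid",       "rs11190604", "HIF1AN",     10L, "G", "A", "0.02-0.7", 0.02, 0.004, "5.7e-9",   -0.012, 0.009, "0.179",
    "palmitoleic acid",       "rs102275",   "FADS1/2",    11L, "C", "T", "0.15-1.0", 0.02, 0.003, "6.6e-13",  -0.011, 0.007, "0.136",
    "oleic acid",             "rs102275",   "FADS1/2",    11L, "C", "T", "0.3-2.1",  0.23, 0.020, "2.2e-32",  -0.011, 0.007, "0.136",
    "palmitic acid",          "rs2391388",  "ALG14",       1L, "C", "A", "0.2-1.0",  0.18, 0.030, "2.7e-11",   0.013, 0.007, "0.087",
    "stearic acid",           "rs6675668",  "ALG14",       1L, "G", "T", "0.4-1.4",  0.17, 0.020, "2.2e-18",  -0.011, 0.007, "0.121",
    "stearic acid",           "rs11119805", "LPGAT1",      1L, "T", "A", "0.01-0.7", 0.17, 0.030, "2.8e-9",    0.008, 0.011, "0.435",
    "stearic acid",           "rs102275",   "FADS1/2",    11L, "T", "C", "0.3-1.2",  0.18, 0.020, "1.3e-20",   0.011, 0.007, "0.136"
  )
  tbl <- tbl[c(assoc_columns())]
  validate_association_table(derive_assoc_columns(tbl))
}

#' Fatty acid classes and SD scale factors
#'
#' One row per fatty acid: its class and the SD scale factor (% of total
#' plasma fatty acids corresponding to 1 SD of its plasma level, taken from
#' the largest cohort of the exposure GWASs). Causal estimates are expressed
#' per 1 SD by multiplying each per-unit Wald ratio by this factor.
#'
#' @return A tibble with columns `exposure`, `fa_class`, `sd_scale`.
#' @export
fa_sd_scales <- function() {
  tibble::tribble(
    ~exposure,               ~fa_class,   ~sd_scale,
    "alpha-linolenic acid",   "n-3 PUFA",  0.05,
    "eicosapentaenoic acid",  "n-3 PUFA",  0.30,
    "docosapentaenoic acid",  "n-3 PUFA",  0.17,
    "docosahexaenoic acid",   "n-3 PUFA",  0.89,
    "linoleic acid",          "n-6 PUFA",  2.69,
    "arachidonic acid",       "n-6 PUFA",  1.96,
    "palmitoleic acid",       "n-7 MUFA",  0.18,
    "oleic acid",             "n-9 MUFA",  1.17,
    "palmitic acid",          "SFA",       1.64,
    "stearic acid",           "SFA",       1.19
  )
}

#' Bundled exposures with their instrument sets
#'
#' Joins [fa_sd_scales()] with [fa_af_associations()] into one row per fatty
#' acid with a nested `instruments` list-column, checking the instrument-set
#' invariants: instruments distinct by rsid within an exposure and every
#' instrument genome-wide significant (p < 5e-8) for its exposure.
#'
#' @return A tibble with columns `exposure`, `fa_class`, `sd_scale`, `k`,
#'   `instruments` (list of association tibbles).
#' @export
fa_exposures <- function() {
  tbl <- fa_af_associations()
  nested <- tidyr::nest(tbl, instruments = -"exposure")
  out <- dplyr::left_join(fa_sd_scales(), nested, by = "exposure")
  out$k <- vapply(out$instruments, nrow, integer(1))
  for (i in seq_len(nrow(out))) {
    ins <- out$instruments[[i]]
    if (anyDuplicated(ins$rsid) > 0) {
      abort(paste0("duplicate instrument rsid for ", out$exposure[i]))
    }
    if (any(ins$log10_p_exp >= log10(5e-8))) {
      abort(paste0("instrument below genome-wide significance for ",
                   out$exposure[i]))
    }
  }
  out[c("exposure", "fa_class", "sd_scale", "k", "instruments")]
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` (default lists them).
#' @return Full path(s).
#' @export
mrfa_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mrfa"))
  } else {
    system.file("extdata", file, package = "mrfa", mustWork = TRUE)
  }
}
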