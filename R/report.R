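# End-to-end driver: per-exposure Wald ratios, fixed-effects IVW for every
# exposure, the sensitivity battery (multiplicative random-effects IVW,
# weighted median, MR-Egger) where at least `sensitivity_min_k` instruments
# exist, optional leave-one-out blocks, and a significance tier per primary
# result. Odds ratios are kept at full precision internally and rounded only
# at render time.

normalize_sd_scales <- function(sd_scales) {
  if (is.character(sd_scales) && length(sd_scales) == 1) {
    sd_scales <- unlist(yaml::read_yaml(sd_scales))
  }
  if (is.numeric(sd_scales) && !is.null(names(sd_scales))) {
    sd_scales <- tibble::tibble(exposure = names(sd_scales),
                                sd_scale = unname(sd_scales))
  }
  if (!is.data.frame(sd_scales) ||
      !all(c("exposure", "sd_scale") %in% names(sd_scales))) {
    abort("`sd_scales` must map exposure names to positive SD scale factors")
  }
  if (any(sd_scales$sd_scale <= 0)) abort("sd_scale values must be > 0")
  sd_scales
}

#' Run the full Mendelian randomization analysis
#'
#' For every exposure in `table` (or the subset named in `exposures`):
#' per-SNP Wald ratios on the per-SD scale, then fixed-effects IVW always;
#' when an exposure has at least `sensitivity_min_k` instruments, also
#' multiplicative random-effects IVW, the weighted median (bootstrap SE), and
#' MR-Egger slope + intercept. Each exposure's primary (fixed-effects IVW)
#' p-value receives a significance tier via [classify_significance()].
#' Leave-one-out blocks are computed for the exposures named in `loo`.
#'
#' @param table An association table (default: the bundled fatty acid /
#'   atrial fibrillation instruments, [fa_af_associations()]).
#' @param sd_scales Exposure SD scale factors: a data frame with columns
#'   `exposure` and `sd_scale`, a named numeric vector, or the path to a YAML
#'   file mapping exposure name to scale. Default [fa_sd_scales()].
#' @param exposures Optional character vector restricting the analysis;
#'   unknown names are an error.
#' @param loo Exposures to run leave-one-out for: a character vector, `TRUE`
#'   (all with k >= 2) or `NULL`/`FALSE` (none).
#' @param n_boot,seed Weighted-median bootstrap size and seed; results are
#'   deterministic given `(table, options, seed)`.
#' @param sensitivity_min_k Minimum instrument count for the sensitivity
#'   battery (default 3).
#' @return An object of class `mr_analysis` with components `results` (tibble
#'   of pooled estimates, one row per exposure x method, with `tier` on the
#'   primary rows), `ratios` (per-SNP Wald ratios), `loo` (leave-one-out
#'   rows, possibly empty) and `exposures` (per-exposure k and SD scale).
#'   Use [tidy()], [glance()], [render_report()], [autoplot()].
#' @export
#' @examples
#' fit <- mr_analyze(loo = c("linoleic acid", "palmitoleic acid"), n_boot = 200)
#' tidy(fit)
mr_analyze <- function(table = fa_af_associations(),
                       sd_scales = fa_sd_scales(),
                       exposures = NULL,
                       loo = NULL,
                       n_boot = 10000,
                       seed = 1,
                       sensitivity_min_k = 3) {
  table <- validate_association_table(table)
  sd_scales <- normalize_sd_scales(sd_scales)

  all_exposures <- unique(table$exposure)
  if (is.null(exposures)) exposures <- all_exposures
  unknown <- setdiff(exposures, all_exposures)
  if (length(unknown) > 0) {
    abort(paste0("unknown exposure(s): ", paste(unknown, collapse = ", ")))
  }
  no_scale <- setdiff(exposures, sd_scales$exposure)
  if (length(no_scale) > 0) {
    abort(paste0("no SD scale for exposure(s): ",
                 paste(no_scale, collapse = ", ")))
  }

  if (isTRUE(loo)) loo <- exposures
  if (isFALSE(loo) || is.null(loo)) loo <- character(0)
  unknown_loo <- setdiff(loo, exposures)
  if (length(unknown_loo) > 0) {
    abort(paste0("leave-one-out requested for unknown exposure(s): ",
                 paste(unknown_loo, collapse = ", ")))
  }

  per_exposure <- function(name, idx) {
    rows <- table[table$exposure == name, ]
    scale <- sd_scales$sd_scale[sd_scales$exposure == name][1]
    k <- nrow(rows)
    if (k == 0) abort(paste0("no instruments for ", name))
    ratios <- wald_ratios(rows, scale)
    res <- mr_ivw(ratios, "fixed")
    if (k >= sensitivity_min_k) {
      res <- dplyr::bind_rows(
        res,
        mr_ivw(ratios, "random"),
        mr_weighted_median(ratios, n_boot = n_boot, seed = seed + idx),
        mr_egger(rows, scale)
      )
    }
    res$tier <- ifelse(res$method == "ivw_fixed",
                       classify_significance(res$p), NA_character_)
    list(
      results = dplyr::bind_cols(tibble::tibble(exposure = name), res),
      ratios = dplyr::bind_cols(tibble::tibble(exposure = name), ratios),
      loo = if (name %in% loo && k >= 2) {
        dplyr::bind_cols(tibble::tibble(exposure = name),
                         mr_leave_one_out(ratios))
      },
      meta = tibble::tibble(exposure = name, k = k, sd_scale = scale)
    )
  }

  parts <- purrr::map(seq_along(exposures),
                      function(i) per_exposure(exposures[i], i))
  structure(
    list(
      results = purrr::map_dfr(parts, "results"),
      ratios = purrr::map_dfr(parts, "ratios"),
      loo = purrr::map_dfr(parts, "loo"),
      exposures = purrr::map_dfr(parts, "meta"),
      options = list(n_boot = n_boot, seed = seed,
                     sensitivity_min_k = sensitivity_min_k, loo = loo)
    ),
    class = "mr_analysis"
  )
}

#' Tidy an MR analysis
#'
#' @param x An `mr_analysis` object.
#' @param type `"results"` (pooled estimates; default), `"ratios"` (per-SNP
#'   Wald ratios) or `"loo"` (leave-one-out rows).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_analysis <- function(x, type = c("results", "ratios", "loo"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' One-row summary of an MR analysis
#'
#' @param x An `mr_analysis` object.
#' @param ... Unused.
#' @return A tibble with exposure/SNP counts and primary-tier tallies.
#' @export
glance.mr_analysis <- function(x, ...) {
  primary <- x$results[x$results$method == "ivw_fixed", ]
  tibble::tibble(
    n_exposures = nrow(x$exposures),
    n_snps = dplyr::n_distinct(x$ratios$rsid),
    n_results = nrow(x$results),
    n_significant = sum(primary$tier == "significant"),
    n_suggestive = sum(primary$tier == "suggestive"),
    seed = x$options$seed,
    n_boot = x$options$n_boot
  )
}

#' @export
print.mr_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mr_analysis> %d exposures, %d distinct SNPs; primary tiers: %d significant, %d suggestive\n",
    g$n_exposures, g$n_snps, g$n_significant, g$n_suggestive
  ))
  print(render_report(x), n = Inf)
  invisible(x)
}

format_p <- function(p) {
  ifelse(is.na(p), NA_character_, formatC(signif(p, 2), format = "g"))
}

#' Render an analysis as a publication-style table
#'
#' Formats pooled estimates (and any leave-one-out rows) with odds ratios and
#' confidence limits at two decimals and p-values at two significant figures.
#' Rounding happens only here; the underlying `mr_analysis` keeps full
#' precision.
#'
#' @param x An `mr_analysis` object.
#' @param include_loo Append leave-one-out rows (default `TRUE` when
#'   present)?
#' @return A tibble of formatted character columns: `exposure`, `analysis`,
#'   `k`, `or`, `ci_95`, `p`, `tier`.
#' @export
render_report <- function(x, include_loo = TRUE) {
  fmt <- function(tbl, analysis) {
    tibble::tibble(
      exposure = tbl$exposure,
      analysis = analysis,
      k = tbl$k,
      or = sprintf("%.2f", tbl$or),
      ci_95 = sprintf("%.2f, %.2f", tbl$ci_low, tbl$ci_high),
      p = format_p(tbl$p),
      tier = tbl$tier %||% NA_character_
    )
  }
  main <- fmt(x$results, x$results$method)
  if (include_loo && nrow(x$loo) > 0) {
    loo <- x$loo
    loo$tier <- NA_character_
    main <- dplyr::bind_rows(
      main, fmt(loo, paste0("ivw_fixed (omit ", loo$omitted_rsid, ")"))
    )
  }
  main
}

#' Write a rendered analysis report as TSV
#'
#' @inheritParams render_report
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, include_loo = TRUE) {
  readr::write_tsv(render_report(x, include_loo = include_loo), path,
                   progress = FALSE)
  invisible(path)
}
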