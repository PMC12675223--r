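#' Full agreement report for a classified cohort
#'
#' Computes the overall rate, the non-rejection and rejection stratum rates,
#' the exact-type rate within pathologist-rejection cases, and Cohen's
#' kappa for a flow table. Rates are held at full precision and rounded to
#' one decimal (in percent) only when printed. Kappa is an extension beyond
#' raw agreement rates and is labelled as such in the printout.
#'
#' @param flow A `"banff_flow"` object, or a classified cohort data frame
#'   (in which case the flow table is built first).
#' @return An object of class `"banff_agreement"`: list of stratum results
#'   (each with `rate`, `numerator`, `denominator`) plus `kappa` and
#'   `n_total`.
#' @export
#' @examples
#' cohort <- classify_cohort(load_fixture("table1"))
#' agreement_report(build_flow_table(cohort))
agreement_report <- function(flow) {
  if (is.data.frame(flow)) flow <- build_flow_table(flow)
  stopifnot(inherits(flow, "banff_flow"))
  strata <- c("overall", "non_rejection", "rejection", "exact_type")
  out <- lapply(strata, function(s) {
    tryCatch(agreement_rate(flow, s), error = function(e) NULL)
  })
  names(out) <- strata
  out$kappa <- cohen_kappa(flow)
  out$n_total <- flow$n_total
  structure(out, class = "banff_agreement")
}

#' @export
print.banff_agreement <- function(x, ...) {
  cat("Pathologist vs automated-diagnosis agreement (n =", x$n_total, ")\n")
  fmt <- function(s, label) {
    if (is.null(x[[s]])) {
      cat(sprintf("  %-28s (empty stratum)\n", label))
    } else {
      cat(sprintf("  %-28s %5.1f%%  (%d/%d)\n", label, 100 * x[[s]]$rate,
                  x[[s]]$numerator, x[[s]]$denominator))
    }
  }
  fmt("overall", "overall")
  fmt("non_rejection", "non-rejection stratum")
  fmt("rejection", "rejection stratum")
  fmt("exact_type", "exact type within rejection")
  cat(sprintf("  %-28s %5.3f  (chance-corrected extension)\n",
              "Cohen's kappa", x$kappa))
  invisible(x)
}
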