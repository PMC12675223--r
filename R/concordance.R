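# Pathologist-versus-engine agreement: flow (Sankey) tables, stratified
# agreement rates, chance-corrected agreement, and discrepancy extraction.

#' Build a pathologist-by-engine flow table
#'
#' Cross-tabulates the canonical pathologist diagnosis against the engine
#' primary category. Pathologist free-text non-rejection entities (recurrent
#' glomerulonephritis, BK virus nephropathy, thrombotic microangiopathy,
#' toxic tubulopathy, ...) collapse into an `"other"` row on the
#' non-rejection side; the engine never emits `"other"`.
#'
#' @param cohort Data frame with `pathologist_dx` and `engine_dx` columns
#'   (run [classify_cohort()] first, or supply `engine_dx` directly).
#' @return An object of class `"banff_flow"`: list with `counts` (matrix,
#'   rows = pathologist, columns = engine) and `n_total`.
#' @export
#' @examples
#' cohort <- classify_cohort(load_fixture("table1"))
#' build_flow_table(cohort)
build_flow_table <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("pathologist_dx", "engine_dx") %in% names(cohort))) {
    stop("cohort must carry both pathologist_dx and engine_dx")
  }
  path <- parse_diagnosis_label(cohort$pathologist_dx)
  eng <- as.character(cohort$engine_dx)
  bad <- which(is.na(path) | is.na(eng))
  if (length(bad) > 0) {
    stop("missing diagnosis label for record(s): ",
         paste(cohort$record_id[bad], collapse = ", "))
  }
  levels_all <- c(diagnosis_categories(), "other")
  counts <- table(factor(path, levels = levels_all),
                  factor(eng, levels = diagnosis_categories()))
  counts <- unclass(counts)
  dimnames(counts) <- list(pathologist = rownames(counts),
                           engine = colnames(counts))
  structure(list(counts = counts, n_total = nrow(cohort)),
            class = "banff_flow")
}

#' Construct a flow table from a count matrix
#'
#' For agreement arithmetic on pre-aggregated counts (e.g. published
#' contingency totals) rather than record-level data.
#'
#' @param counts Matrix of non-negative integers; dimnames give the
#'   pathologist (rows) and engine (columns) labels, drawn from
#'   [diagnosis_categories()] plus `"other"` on the pathologist side.
#' @return A `"banff_flow"` object.
#' @export
flow_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  names(dimnames(counts)) <- c("pathologist", "engine")
  structure(list(counts = counts, n_total = sum(counts)),
            class = "banff_flow")
}

#' @export
print.banff_flow <- function(x, ...) {
  cat("Pathologist x engine diagnosis flow,", x$n_total, "biopsies\n")
  keep_r <- rowSums(x$counts) > 0
  keep_c <- colSums(x$counts) > 0
  print(x$counts[keep_r, keep_c, drop = FALSE])
  invisible(x)
}

level_of_label <- function(labels) {
  ifelse(labels %in% REJECTION_CATEGORIES, "rejection", "non-rejection")
}

#' Stratified pathologist-engine agreement rate
#'
#' * `"overall"` — fraction of biopsies with identical base-category labels.
#' * `"non_rejection"` — among biopsies the pathologist placed at the
#'   non-rejection level (borderline, IFTA, C4d-without-rejection, other
#'   entities and no rejection), the fraction the engine also placed at the
#'   non-rejection level.
#' * `"rejection"` — among pathologist rejection-level biopsies, the
#'   fraction the engine also called rejection (any type).
#' * `"exact_type"` — among pathologist rejection-level biopsies, the
#'   fraction with the identical rejection category.
#'
#' Rates are returned at full precision; round only for presentation.
#'
#' @param flow A `"banff_flow"` object.
#' @param stratum One of `"overall"`, `"non_rejection"`, `"rejection"`,
#'   `"exact_type"`.
#' @return List with `rate`, `numerator`, `denominator`, `stratum`.
#' @export
#' @examples
#' flow <- flow_from_counts(matrix(c(40, 10, 10, 40), 2, 2,
#'   dimnames = list(c("A-AMR", "no-rejection"), c("A-AMR", "no-rejection"))))
#' agreement_rate(flow, "overall")
agreement_rate <- function(flow, stratum = c("overall", "non_rejection",
                                             "rejection", "exact_type")) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(flow, "banff_flow"))
  counts <- flow$counts
  rlev <- level_of_label(rownames(counts))
  clev <- level_of_label(colnames(counts))
  if (stratum == "overall") {
    den <- sum(counts)
    num <- sum(counts[outer(rownames(counts), colnames(counts), "==")])
  } else if (stratum == "non_rejection") {
    den <- sum(counts[rlev == "non-rejection", , drop = FALSE])
    num <- sum(counts[rlev == "non-rejection", clev == "non-rejection",
                      drop = FALSE])
  } else if (stratum == "rejection") {
    den <- sum(counts[rlev == "rejection", , drop = FALSE])
    num <- sum(counts[rlev == "rejection", clev == "rejection", drop = FALSE])
  } else {
    sub <- counts[rlev == "rejection", , drop = FALSE]
    den <- sum(sub)
    num <- sum(sub[outer(rownames(sub), colnames(sub), "==")])
  }
  if (den == 0) {
    stop("agreement rate undefined: empty '", stratum, "' stratum")
  }
  list(rate = num / den, numerator = num, denominator = den,
       stratum = stratum)
}

#' Cohen's kappa for a flow table
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) over the union of
#' pathologist and engine labels. This statistic is an extension of the
#' concordance analysis (the published comparison reports raw agreement
#' rates only) and reports are labelled accordingly.
#'
#' @param flow A `"banff_flow"` object with `n_total >= 1`.
#' @return Kappa as a single number.
#' @export
#' @examples
#' cohen_kappa(flow_from_counts(matrix(c(40, 10, 10, 40), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b")))))  # 0.6
cohen_kappa <- function(flow) {
  stopifnot(inherits(flow, "banff_flow"))
  if (flow$n_total < 1) stop("kappa undefined for an empty table")
  labels <- union(rownames(flow$counts), colnames(flow$counts))
  sq <- matrix(0, length(labels), length(labels),
               dimnames = list(labels, labels))
  sq[rownames(flow$counts), colnames(flow$counts)] <- flow$counts
  n <- sum(sq)
  p_o <- sum(diag(sq)) / n
  p_e <- sum(rowSums(sq) * colSums(sq)) / n^2
  if (p_e >= 1) stop("kappa undefined: expected agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' Extract discrepancy records
#'
#' Records whose canonical pathologist label and engine primary category
#' differ at the base-category level, partitioned per category family (AMR,
#' TCMR) into a pathologist-only panel (pathologist assigns the family, the
#' engine does not) and an engine-only panel (the reverse), mirroring the
#' layout of published discrepancy tables. A record can appear in both
#' family partitions (pathologist AMR reclassified as TCMR, say).
#'
#' @param cohort Data frame with `pathologist_dx` and `engine_dx`.
#' @return The disagreeing records with columns `dx_family` (`"AMR"` or
#'   `"TCMR"`; `NA` for disagreements touching neither family) and `panel`
#'   (`"pathologist-only"` / `"engine-only"`) appended. Zero rows under
#'   perfect agreement.
#' @export
discrepancy_records <- function(cohort) {
  stopifnot(all(c("pathologist_dx", "engine_dx") %in% names(cohort)))
  path <- parse_diagnosis_label(cohort$pathologist_dx)
  eng <- as.character(cohort$engine_dx)
  disagree <- which(path != eng)
  pieces <- list()
  for (fam in c("AMR", "TCMR")) {
    pf <- category_family(path) == fam
    ef <- category_family(eng) == fam
    for (panel in c("pathologist-only", "engine-only")) {
      keep <- intersect(disagree,
                        which(if (panel == "pathologist-only") pf & !ef
                              else ef & !pf))
      if (length(keep) > 0) {
        piece <- cohort[keep, , drop = FALSE]
        piece$dx_family <- fam
        piece$panel <- panel
        pieces[[length(pieces) + 1L]] <- piece
      }
    }
  }
  neither <- setdiff(disagree, which(category_family(path) != "none" |
                                       category_family(eng) != "none"))
  if (length(neither) > 0) {
    piece <- cohort[neither, , drop = FALSE]
    piece$dx_family <- NA_character_
    piece$panel <- NA_character_
    pieces[[length(pieces) + 1L]] <- piece
  }
  if (length(pieces) == 0) {
    out <- cohort[0, , drop = FALSE]
    out$dx_family <- character(0)
    out$panel <- character(0)
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Export a flow table as long-format CSV
#'
#' Columns `pathologist`, `engine`, `count`; zero cells are omitted.
#'
#' @param flow A `"banff_flow"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  stopifnot(inherits(flow, "banff_flow"))
  long <- as.data.frame(as.table(flow$counts), stringsAsFactors = FALSE)
  names(long) <- c("pathologist", "engine", "count")
  long <- long[long$count > 0, , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Flow table as a Sankey node/link structure
#'
#' @param flow A `"banff_flow"` object.
#' @return A list with `nodes` (data frame: `name`, `side`) and `links`
#'   (data frame: `source`, `target`, `value`; zero-based node indices),
#'   ready for `jsonlite::toJSON()` or any Sankey renderer.
#' @export
flow_sankey_json <- function(flow) {
  stopifnot(inherits(flow, "banff_flow"))
  counts <- flow$counts
  rn <- rownames(counts)[rowSums(counts) > 0]
  cn <- colnames(counts)[colSums(counts) > 0]
  nodes <- data.frame(
    name = c(paste0("pathologist:", rn), paste0("engine:", cn)),
    side = rep(c("pathologist", "engine"), c(length(rn), length(cn))),
    stringsAsFactors = FALSE
  )
  links <- do.call(rbind, lapply(seq_along(rn), function(a) {
    do.call(rbind, lapply(seq_along(cn), function(b) {
      v <- counts[rn[a], cn[b]]
      if (v > 0) data.frame(source = a - 1L,
                            target = length(rn) + b - 1L,
                            value = as.integer(v)) else NULL
    }))
  }))
  if (is.null(links)) {
    links <- data.frame(source = integer(), target = integer(),
                        value = integer())
  }
  list(nodes = nodes, links = links)
}
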