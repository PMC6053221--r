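#' Run the full morphometry pipeline over annotated terminals
#'
#' For every terminal: membrane classification, vesicle distances, glial
#' coverage and apposition-midpoint gaps. Distances are then pooled per
#' condition and compartment into distance distributions with KDE pool
#' peaks and near-membrane counts; conditions are compared pairwise with
#' Fisher's exact test on the near-membrane contingency tables, and
#' per-terminal metrics across conditions with Kruskal-Wallis plus Dunn's
#' post hoc (when at least two conditions are present).
#'
#' @param annotations list of [terminal_annotation()] (conditions mixed
#'   freely).
#' @param tau_az,tau_glial,step,min_run classification parameters, see
#'   [classify_membrane()].
#' @param bin_width histogram bin width (nm).
#' @param threshold near-membrane cutoff (nm, strict `<`).
#' @param min_prominence peak prominence threshold.
#' @return object of class `condition_report` with elements
#'   `per_terminal`, `distances`, `gaps` (data frames), `pools` (list of
#'   [pool_distribution()] keyed `condition.compartment`), `peaks` (data
#'   frame), `near_counts` (list plus `contingency` data frame of pairwise
#'   Fisher results), and `group_stats` (data frame).
#' @export
condition_report <- function(annotations, tau_az = 30, tau_glial = 30,
                             step = 1, min_run = 10, bin_width = 10,
                             threshold = 50, min_prominence = 0.05) {
  stopifnot(length(annotations) > 0L)
  per_terminal <- vector("list", length(annotations))
  dists <- vector("list", length(annotations))
  gaps <- vector("list", length(annotations))
  for (i in seq_along(annotations)) {
    ann <- annotations[[i]]
    seg <- classify_membrane(ann, tau_az = tau_az, tau_glial = tau_glial,
                             step = step, min_run = min_run)
    vd <- vesicle_distances(ann, seg)
    vd$condition <- ann$condition
    dists[[i]] <- vd
    gp <- midpoint_gap_distances(ann, seg)
    if (nrow(gp)) gp$condition <- ann$condition
    gaps[[i]] <- gp
    per_terminal[[i]] <- data.frame(
      terminal_id = ann$terminal_id,
      condition = ann$condition,
      n_vesicles = nrow(ann$vesicles),
      perimeter_length_nm = seg$perimeter_length,
      active_zone_length_nm = seg$active_zone_length,
      glial_facing_length_nm = seg$glial_facing_length,
      glial_coverage = glial_coverage_fraction(seg),
      n_glial_regions = sum(seg$regions$compartment == "glial_facing"))
  }
  per_terminal <- do.call(rbind, per_terminal)
  distances <- do.call(rbind, dists)
  gaps <- do.call(rbind, gaps[lengths(gaps) > 0 & vapply(gaps, nrow, 0L) > 0])

  conditions <- unique(per_terminal$condition)
  compartments <- c(active_zone = "d_active_zone", glial_facing = "d_glial")
  pools <- list()
  near <- list()
  peaks <- list()
  for (cond in conditions) {
    for (cmp in names(compartments)) {
      d <- distances[distances$condition == cond, compartments[[cmp]]]
      d <- d[!is.na(d)]
      if (length(d) < 2L) next
      key <- paste(cond, cmp, sep = ".")
      pools[[key]] <- pool_distribution(
        d, bin_width = bin_width, min_prominence = min_prominence,
        compartment = cmp, condition = cond)
      near[[key]] <- near_membrane_fraction(d, threshold = threshold,
                                            compartment = cmp,
                                            condition = cond)
      pk <- pools[[key]]$peaks
      if (nrow(pk)) {
        pk <- cbind(condition = cond, compartment = cmp, pk)
        peaks[[key]] <- pk
      }
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, c(peaks, make.row.names = FALSE))
           else data.frame(condition = character(0), compartment = character(0),
                           peak_nm = numeric(0), density_per_nm = numeric(0),
                           probability_pct = numeric(0))

  contingency <- list()
  if (length(conditions) >= 2L) {
    prs <- utils::combn(conditions, 2L)
    for (cmp in names(compartments)) {
      for (j in seq_len(ncol(prs))) {
        pair <- prs[, j]
        tb <- try(build_condition_contingency(near, pair, compartment = cmp),
                  silent = TRUE)
        if (inherits(tb, "try-error")) next
        fr <- fisher_exact_2x2(tb)
        contingency[[length(contingency) + 1L]] <- data.frame(
          compartment = cmp, condition_a = pair[1L], condition_b = pair[2L],
          within_a = tb[1L, 1L], total_a = sum(tb[1L, ]),
          within_b = tb[2L, 1L], total_b = sum(tb[2L, ]),
          fraction_a = tb[1L, 1L] / sum(tb[1L, ]),
          fraction_b = tb[2L, 1L] / sum(tb[2L, ]),
          odds_ratio = fr$odds_ratio, p_two_sided = fr$p_two_sided)
      }
    }
  }
  contingency <- if (length(contingency)) do.call(rbind, contingency)
                 else NULL

  group_stats <- NULL
  grp_sizes <- table(per_terminal$condition)
  if (length(conditions) >= 2L && all(grp_sizes >= 2L)) {
    metrics <- c("n_vesicles", "perimeter_length_nm", "active_zone_length_nm",
                 "glial_coverage")
    rows <- list()
    for (m in metrics) {
      groups <- split(per_terminal[[m]], per_terminal$condition)
      cmpres <- kruskal_wallis_dunn(groups, metric = m)
      pw <- cmpres$pairwise
      pw <- cbind(metric = m, H = cmpres$H, p_omnibus = cmpres$p_omnibus, pw)
      rows[[m]] <- pw
    }
    if (!is.null(gaps) && nrow(gaps) > 0L &&
        all(table(factor(gaps$condition, levels = conditions)) >= 2L)) {
      groups <- split(gaps$midpoint_gap_nm, gaps$condition)
      cmpres <- kruskal_wallis_dunn(groups, metric = "midpoint_gap_nm")
      rows$midpoint_gap_nm <- cbind(metric = "midpoint_gap_nm", H = cmpres$H,
                                    p_omnibus = cmpres$p_omnibus,
                                    cmpres$pairwise)
    }
    group_stats <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  structure(list(per_terminal = per_terminal, distances = distances,
                 gaps = gaps, pools = pools, peaks = peaks,
                 near_counts = near, contingency = contingency,
                 group_stats = group_stats,
                 params = list(tau_az = tau_az, tau_glial = tau_glial,
                               step = step, min_run = min_run,
                               bin_width = bin_width, threshold = threshold,
                               min_prominence = min_prominence)),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report: %d terminals, %d vesicles, conditions: %s>\n",
              nrow(x$per_terminal), nrow(x$distances),
              paste(unique(x$per_terminal$condition), collapse = ", ")))
  invisible(x)
}

near_counts_table <- function(near) {
  do.call(rbind, lapply(unname(near), function(x) data.frame(
    condition = x$condition, compartment = x$compartment,
    n_within = x$n_within, n_total = x$n_total,
    fraction = x$fraction, threshold_nm = x$threshold)))
}

#' Write a condition report as TSV tables
#'
#' One tab-separated file per report section: per-terminal metrics, pooled
#' distance records, pool-peak table (peak nm plus probability percent),
#' near-membrane counts, pairwise contingency tests, apposition gaps and
#' group statistics. Sections absent from the report are skipped.
#'
#' @param report a [condition_report()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_condition_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
  }
  emit(report$per_terminal, "per_terminal_metrics")
  emit(report$distances, "pooled_distances")
  emit(report$peaks, "pool_peaks")
  if (length(report$near_counts))
    emit(near_counts_table(report$near_counts), "near_membrane_counts")
  emit(report$contingency, "contingency")
  if (!is.null(report$gaps) && nrow(report$gaps)) emit(report$gaps, "gap_regions")
  emit(report$group_stats, "group_stats")
  invisible(written)
}
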