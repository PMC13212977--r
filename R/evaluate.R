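#' Build cross-validation folds for one blinding scenario
#'
#' Four scenarios control what the test folds may share with training:
#'
#' * `unblinded`: pairs are partitioned into 10 parts, approximately
#'   stratified so each cell's (and, in expectation, each drug's) pairs are
#'   spread over all parts; fold f tests on part f, validates on the next
#'   part (cyclic) and trains on the remaining 8 (8:1:1).
#' * `cell_blind` / `drug_blind`: the entity set is partitioned into 10
#'   parts; pairs follow their entity, so no test cell (or drug) is ever
#'   seen in training or validation.
#' * `strict_blind`: cells into 5 parts and drugs into 5 parts; each of the
#'   25 folds tests on one (cell part x drug part) block, validates on the
#'   (next cell part x next drug part) block (cyclic), and trains on the
#'   remaining 3 x 3 blocks (3:1:1 per axis). Pairs crossing blind
#'   boundaries are discarded from that fold.
#'
#' @param table A `response_table` (deduplicated).
#' @param scenario One of `"unblinded"`, `"cell_blind"`, `"drug_blind"`,
#'   `"strict_blind"`.
#' @param seed Integer seed; folds are deterministic given the seed.
#' @return A `split_plan`: list with `scenario`, `seed`, `folds` (list of
#'   lists with integer record indices `train`, `val`, `test`).
#' @export
make_splits <- function(table,
                        scenario = c("unblinded", "cell_blind", "drug_blind",
                                     "strict_blind"),
                        seed = 1L) {
  scenario <- match.arg(scenario)
  r <- table$records
  n <- nrow(r)
  set.seed(as.integer(seed))
  cells <- unique(r$cell_id); drugs <- unique(r$drug_id)
  if (scenario != "unblinded" && (length(cells) < 10 || length(drugs) < 10))
    stop("blind scenarios need >= 10 cells and >= 10 drugs")

  folds <- switch(scenario,
    unblinded = {
      # per-cell round-robin deal keeps every cell (and approximately every
      # drug) represented in all 10 parts
      part <- integer(n)
      start <- 0L
      for (cid in sample(cells)) {
        idx <- sample(which(r$cell_id == cid))
        part[idx] <- ((start + seq_along(idx) - 1L) %% 10L) + 1L
        start <- start + length(idx)
      }
      lapply(1:10, function(f) {
        v <- (f %% 10L) + 1L
        list(test = which(part == f), val = which(part == v),
             train = which(!part %in% c(f, v)))
      })
    },
    cell_blind = entity_folds(r$cell_id, cells, 10L),
    drug_blind = entity_folds(r$drug_id, drugs, 10L),
    strict_blind = {
      cpart <- deal_parts(sample(cells), 5L)
      dpart <- deal_parts(sample(drugs), 5L)
      ci <- cpart[r$cell_id]; di <- dpart[r$drug_id]
      out <- list()
      for (i in 1:5) for (j in 1:5) {
        iv <- (i %% 5L) + 1L; jv <- (j %% 5L) + 1L
        out[[length(out) + 1L]] <- list(
          test = unname(which(ci == i & di == j)),
          val = unname(which(ci == iv & di == jv)),
          train = unname(which(!(ci %in% c(i, iv)) & !(di %in% c(j, jv)))))
      }
      out
    })
  structure(list(scenario = scenario, seed = as.integer(seed), folds = folds),
            class = "split_plan")
}

deal_parts <- function(ids, k) {
  stats::setNames(((seq_along(ids) - 1L) %% k) + 1L, ids)
}

entity_folds <- function(entity_of_record, entities, k) {
  part <- deal_parts(sample(entities), k)
  p <- part[entity_of_record]
  lapply(seq_len(k), function(f) {
    v <- (f %% k) + 1L
    list(test = unname(which(p == f)), val = unname(which(p == v)),
         train = unname(which(!p %in% c(f, v))))
  })
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) lengths(f[c("train", "val", "test")]),
                  integer(3))
  cat("split_plan:", x$scenario, "-", length(x$folds), "folds; mean sizes",
      paste(c("train", "val", "test"), round(rowMeans(sizes)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a split plan as JSON
#'
#' @param plan A `split_plan`.
#' @param path JSON path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(scenario = plan$scenario, seed = plan$seed,
                            folds = plan$folds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @return `read_split_plan()` returns the restored `split_plan`.
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_or_len(obj$folds)), function(i) {
    f <- if (is.data.frame(obj$folds)) obj$folds[i, ] else obj$folds[[i]]
    list(train = as.integer(unlist(f$train)),
         val = as.integer(unlist(f$val)),
         test = as.integer(unlist(f$test)))
  })
  structure(list(scenario = obj$scenario, seed = as.integer(obj$seed),
                 folds = folds), class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Regression metrics, optionally per cell or per drug
#'
#' Computes RMSE, Pearson (PCC) and Spearman (SCC, average-rank ties)
#' correlations between predictions and observed values. With `group_by`,
#' the same metrics are computed within each entity's pairs; groups with
#' fewer than 3 pairs are excluded (rank correlation is not meaningful
#' below that).
#'
#' @param pred,truth Aligned numeric vectors (n >= 2).
#' @param group_by Optional character vector of entity ids (same length) to
#'   group metrics by.
#' @return A `metrics_report`: list with `rmse`, `pcc`, `scc`, `n`, and
#'   `per_group` (data frame) when grouped. Zero-variance truth yields `NA`
#'   correlations with RMSE still reported.
#' @export
compute_metrics <- function(pred, truth, group_by = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  one <- function(p, y) {
    rmse <- sqrt(mean((p - y)^2))
    if (stats::sd(y) == 0 || stats::sd(p) == 0) {
      c(rmse = rmse, pcc = NA_real_, scc = NA_real_)
    } else {
      c(rmse = rmse,
        pcc = stats::cor(p, y),
        scc = stats::cor(rank(p, ties.method = "average"),
                         rank(y, ties.method = "average")))
    }
  }
  overall <- one(pred, truth)
  per_group <- NULL
  if (!is.null(group_by)) {
    keep <- names(which(table(group_by) >= 3))
    rows <- lapply(keep, function(g) {
      i <- group_by == g
      m <- one(pred[i], truth[i])
      data.frame(group = g, n = sum(i), rmse = m["rmse"], pcc = m["pcc"],
                 scc = m["scc"], row.names = NULL)
    })
    per_group <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(0), n = integer(0), rmse = numeric(0),
                 pcc = numeric(0), scc = numeric(0))
  }
  structure(list(rmse = unname(overall["rmse"]), pcc = unname(overall["pcc"]),
                 scc = unname(overall["scc"]), n = length(pred),
                 per_group = per_group),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: n=%d RMSE=%.4f PCC=%.4f SCC=%.4f\n",
              x$n, x$rmse, x$pcc, x$scc))
  if (!is.null(x$per_group))
    cat("  per-group metrics for", nrow(x$per_group), "entities\n")
  invisible(x)
}

#' One-tailed Mann-Whitney comparison of two metric samples
#'
#' Tests whether model A's metric replicates are better than model B's in
#' the stated direction (`"lower"` for error metrics such as RMSE,
#' `"higher"` for correlation metrics). Exact p-values are used for small
#' samples (combined n <= 20) without ties, the normal approximation with
#' tie correction otherwise.
#'
#' @param metric_samples_A,metric_samples_B Numeric vectors (>= 3 replicates
#'   each).
#' @param better `"lower"` or `"higher"`.
#' @return List with `p_value`, `statistic` and `flag` (non-NULL when the
#'   identical-constant convention p = 0.5 is applied).
#' @export
compare_models <- function(metric_samples_A, metric_samples_B,
                           better = c("lower", "higher")) {
  better <- match.arg(better)
  a <- metric_samples_A; b <- metric_samples_B
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::sd(c(a, b)) == 0)
    return(list(p_value = 0.5, statistic = NA_real_,
                flag = "identical constant samples"))
  alt <- if (better == "lower") "less" else "greater"
  exact <- (length(a) + length(b) <= 20) && !any(duplicated(c(a, b)))
  w <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                           exact = exact, correct = TRUE))
  list(p_value = w$p.value, statistic = unname(w$statistic), flag = NULL)
}

#' Responder vs non-responder analysis of predicted responses
#'
#' For clinical-style validation: responders (complete/partial response)
#' should receive lower predicted ln(IC50) than non-responders
#' (stable/progressive disease). Effect size is the difference of class
#' means; significance is a one-tailed Mann-Whitney test that responders'
#' predictions are lower.
#'
#' @param predictions Numeric vector of predicted responses.
#' @param responder_labels Logical vector (TRUE = responder), same length.
#' @return List with `effect_size` (mean(responders) - mean(non-responders)),
#'   `p_value`, and class sizes.
#' @export
responder_analysis <- function(predictions, responder_labels) {
  stopifnot(length(predictions) == length(responder_labels))
  resp <- predictions[responder_labels]
  non <- predictions[!responder_labels]
  if (length(resp) == 0L || length(non) == 0L)
    stop("both responder and non-responder classes must be non-empty")
  exact <- (length(resp) + length(non) <= 20) &&
    !any(duplicated(c(resp, non)))
  w <- suppressWarnings(stats::wilcox.test(resp, non, alternative = "less",
                                           exact = exact))
  list(effect_size = mean(resp) - mean(non), p_value = w$p.value,
       n_responders = length(resp), n_non_responders = length(non))
}

#' Per-entity response distribution statistics
#'
#' For each cell (or drug): count, mean and sample standard deviation of
#' ln(IC50); Sarle's bimodality coefficient with small-sample correction,
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with g1 the sample
#' skewness and g2 the sample excess kurtosis; and density coverage, the
#' overlap coefficient between the entity's Gaussian kernel density
#' (Silverman bandwidth) and the global density on a common grid.
#' Bimodality and density coverage are `NA` for entities with fewer than 4
#' values.
#'
#' @param table A `response_table`.
#' @param by `"cell"` or `"drug"`.
#' @return Data frame with one row per entity: `id`, `count`, `mean`, `sd`,
#'   `bimodality`, `density_coverage`.
#' @export
entity_statistics <- function(table, by = c("cell", "drug")) {
  by <- match.arg(by)
  r <- table$records
  key <- if (by == "cell") r$cell_id else r$drug_id
  ids <- unique(key)
  all_vals <- r$ln_ic50
  grid <- seq(min(all_vals) - stats::sd(all_vals),
              max(all_vals) + stats::sd(all_vals), length.out = 512)
  dx <- grid[2] - grid[1]
  dens_global <- density_on_grid(all_vals, grid)
  rows <- lapply(ids, function(id) {
    v <- all_vals[key == id]
    n <- length(v)
    bim <- cov <- NA_real_
    if (n >= 4 && stats::sd(v) > 0) {
      g1 <- e1071::skewness(v, type = 2)
      g2 <- e1071::kurtosis(v, type = 2)
      bim <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
      cov <- sum(pmin(density_on_grid(v, grid), dens_global)) * dx
    }
    data.frame(id = id, count = n, mean = mean(v),
               sd = if (n > 1) stats::sd(v) else 0,
               bimodality = bim, density_coverage = cov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

density_on_grid <- function(v, grid) {
  d <- stats::density(v, bw = "nrd0", from = min(grid), to = max(grid),
                      n = length(grid))
  d$y
}
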