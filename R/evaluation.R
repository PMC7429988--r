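#' Dice similarity coefficient
#'
#' `DC = 2 |A intersect B| / (|A| + |B|)` between two binary volumes on one
#' grid. Two empty masks count as perfect agreement on absence (DC = 1);
#' this convention is flagged where it occurs in experiment reports.
#'
#' @param pred,ref binary arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) {
    stop("shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(ref), collapse = "x"))
  }
  a <- pred != 0
  b <- ref != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Majority-vote consensus of observer masks
#'
#' A voxel enters the consensus when it is set in strictly more than half of
#' the observer masks (with three observers: at least two). Even-observer
#' ties therefore resolve to background.
#'
#' @param observer_masks list of >= 2 binary arrays on one grid.
#' @return Integer consensus mask.
#' @export
majority_vote <- function(observer_masks) {
  if (length(observer_masks) < 2L) stop("need at least 2 observer masks")
  d <- dim(observer_masks[[1]])
  ok <- vapply(observer_masks, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("grid mismatch across observer masks")
  votes <- Reduce(`+`, lapply(observer_masks, function(m) (m != 0) + 0))
  array(as.integer(votes > length(observer_masks) / 2), d)
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided signed-rank test on paired per-case Dice coefficients:
#' zero differences are dropped, tied absolute differences are mid-ranked,
#' the null distribution is enumerated exactly over all 2^n sign assignments
#' for n <= `exact_limit`, and a tie-corrected, continuity-corrected normal
#' approximation with an Edgeworth kurtosis refinement is used above. If every difference is zero the
#' result is flagged degenerate instead of carrying a p-value.
#'
#' @param dc_a,dc_b equal-length (>= 5) per-case score vectors, paired by
#'   case.
#' @param exact_limit largest n for exact enumeration (default 12).
#' @return list with `statistic` (sum of positive ranks), `p_value`,
#'   `method` ("exact" or "normal"), `n` (nonzero differences), and
#'   `degenerate`.
#' @export
compare_models <- function(dc_a, dc_b, exact_limit = 12L) {
  if (length(dc_a) != length(dc_b)) stop("paired samples must have equal length")
  if (length(dc_a) < 5L) stop("need at least 5 paired cases")
  d <- dc_a - dc_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "degenerate", n = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))                       # mid-ranks on ties
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wall <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(wall <= w), mean(wall >= w)))
    method <- "exact"
  } else {
    # W = sum r_i B_i with B_i iid Bernoulli(1/2): moments from the actual
    # (mid-)ranks handle ties exactly; an Edgeworth kurtosis term plus
    # continuity correction keeps the tail error well below 0.01 at n = 12
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    g2 <- (-sum(r^4) / 8) / sig2^2
    Fw <- function(x) {
      z <- (x - mu) / sqrt(sig2)
      stats::pnorm(z) - stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
    }
    pl <- Fw(w + 0.5)
    ph <- 1 - Fw(w - 0.5)
    p <- min(1, max(2 * min(pl, ph), 1e-300))
    method <- "normal"
  }
  list(statistic = w, p_value = p, method = method, n = n, degenerate = FALSE)
}

#' Proportional train/validation/test split
#'
#' Emulates a 40/10/30 patient split proportionally at any cohort size, with
#' a seeded shuffle; the three id sets are disjoint and cover the cohort.
#'
#' @param ids study identifiers.
#' @param fractions relative set sizes (train, validation, test).
#' @param seed shuffle seed.
#' @return A `split_spec` with `train_ids`, `val_ids`, `test_ids`.
#' @export
make_split <- function(ids, fractions = c(40, 10, 30), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0), sum(fractions) > 0)
  n <- length(ids)
  sh <- with_seed(seed, sample(ids))
  prop <- fractions / sum(fractions)
  n_tr <- max(1L, round(n * prop[1]))
  n_va <- max(0L, round(n * prop[2]))
  if (n_tr + n_va >= n) {
    n_va <- max(0L, n - n_tr - 1L)
  }
  split <- structure(
    list(train_ids = sh[seq_len(n_tr)],
         val_ids = if (n_va > 0) sh[n_tr + seq_len(n_va)] else character(0),
         test_ids = sh[(n_tr + n_va + 1L):n],
         seed = as.integer(seed)),
    class = "split_spec"
  )
  split
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> ", length(x$train_ids), " train / ", length(x$val_ids),
      " validation / ", length(x$test_ids), " test\n", sep = "")
  invisible(x)
}

cohort_ids <- function(cohort) {
  vapply(cohort, function(e) e$study$study_id, character(1))
}

#' Run the experiment grid
#'
#' Trains one network per model spec on the training studies, monitors the
#' validation studies, and scores the test studies by per-case full-volume
#' Dice. All models share the training seed, so per-case test scores are
#' paired across models for [compare_models()]. A model run that fails is
#' recorded as failed, not dropped.
#'
#' @param cohort list of study entries (`study` + `masks`).
#' @param model_specs list of [model_spec()]s.
#' @param split a [make_split()] over the cohort ids.
#' @param tc a [train_config()].
#' @param net_config_fn function(channel names) -> [network_config()];
#'   defaults to [small_network_config()].
#' @param train_dice also report mean Dice over the training studies
#'   (default TRUE).
#' @return A `pqseg_report`: a tibble with one row per model (per-case test
#'   Dice in a list column, means, SD, status) carrying the trained models
#'   and the split as attributes.
#' @export
run_experiment_grid <- function(cohort, model_specs, split, tc,
                                net_config_fn = small_network_config,
                                train_dice = TRUE) {
  ids <- cohort_ids(cohort)
  stopifnot(inherits(split, "split_spec"))
  if (!setequal(c(split$train_ids, split$val_ids, split$test_ids), ids)) {
    stop("split does not cover the cohort ids exactly")
  }
  pick <- function(set) cohort[ids %in% set]
  co_tr <- pick(split$train_ids)
  co_va <- pick(split$val_ids)
  co_te <- pick(split$test_ids)

  rows <- vector("list", length(model_specs))
  models <- vector("list", length(model_specs))
  for (i in seq_along(model_specs)) {
    sp <- model_specs[[i]]
    res <- tryCatch({
      net <- build_network(net_config_fn(sp$input_channels),
                           seed = seed_stream(tc$seed, 1000L + i))
      tr <- train_model(net, co_tr, co_va, sp, tc)
      score <- function(entries) vapply(entries, function(e) {
        dice(predict_study(tr$model, e$study, sp)$binary_mask,
             e$masks$masks[[sp$target_mask]])
      }, numeric(1))
      test_dc <- score(co_te)
      both_empty <- vapply(co_te, function(e) {
        sum(e$masks$masks[[sp$target_mask]]) == 0L
      }, logical(1))
      train_dc <- if (train_dice) mean(score(co_tr)) else NA_real_
      models[[i]] <- tr$model
      tibble::tibble(
        model_id = sp$model_id, target = sp$target_mask,
        channels = list(sp$input_channels),
        n_train = length(co_tr), n_val = length(co_va), n_test = length(co_te),
        train_mean_dc = train_dc,
        test_mean_dc = mean(test_dc), test_sd_dc = stats::sd(test_dc),
        test_dcs = list(test_dc),
        n_both_empty = sum(both_empty),
        history = list(tr$history), status = "ok"
      )
    }, error = function(e) {
      tibble::tibble(
        model_id = sp$model_id, target = sp$target_mask,
        channels = list(sp$input_channels),
        n_train = length(co_tr), n_val = length(co_va), n_test = length(co_te),
        train_mean_dc = NA_real_, test_mean_dc = NA_real_,
        test_sd_dc = NA_real_, test_dcs = list(numeric(0)),
        n_both_empty = 0L, history = list(NULL),
        status = paste0("failed: ", conditionMessage(e))
      )
    })
    rows[[i]] <- res
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("pqseg_report", class(report))
  attr(report, "split") <- split
  attr(report, "models") <- models
  report
}

#' @export
tidy.pqseg_report <- function(x, ...) {
  df <- tibble::as_tibble(x[c("model_id", "target", "test_dcs")])
  split <- attr(x, "split")
  tidyr::unnest_longer(
    dplyr::mutate(df, case = list(split$test_ids)),
    c("test_dcs", "case")
  )
}

#' @export
glance.pqseg_report <- function(x, ...) {
  tibble::as_tibble(x[c("model_id", "target", "n_train", "n_val", "n_test",
                        "train_mean_dc", "test_mean_dc", "test_sd_dc",
                        "status")])
}

#' Box plot of per-case test Dice by model
#'
#' @param object a `pqseg_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pqseg_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$model_id),
                                   y = .data$test_dcs,
                                   fill = .data$target)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "model", y = "test Dice coefficient", fill = "target") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Write a report as a CSV table
#'
#' Columns mirror the experiment summary: model, set sizes, train DC, test
#' DC and its SD.
#'
#' @param report a `pqseg_report`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(glance(report), path, row.names = FALSE)
  invisible(path)
}
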