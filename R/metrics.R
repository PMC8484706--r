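#' Normalized mean absolute error (percent)
#'
#' `100 * mean(|Q_i - Qhat_i|) / (Max|Q| - Min|Q|)`, where the
#' normalization is the range of the true field's magnitudes within the
#' model being scored. Scale-invariant: rescaling truth and prediction by a
#' common factor leaves it unchanged.
#'
#' @param truth,pred numeric vectors of equal length (scalarized fields).
#' @return NMAE in percent.
#' @export
nmae <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  rng <- max(abs(truth)) - min(abs(truth))
  if (rng <= 0) stop("nmae: degenerate field (zero magnitude range)")
  100 * mean(abs(truth - pred)) / rng
}

#' Mean relative error (percent)
#'
#' `100 * mean( |Q_i - Qhat_i| / |Q_i| )` over points whose true magnitude
#' is at least `floor`; the per-point relative error is unbounded as the
#' true value approaches zero, so near-zero points are excluded and their
#' count reported in the `"excluded"` attribute.
#'
#' @param truth,pred numeric vectors of equal length.
#' @param floor exclusion threshold on `|truth|`; default
#'   `1e-3 * max(|truth|)`.
#' @return MRE in percent, with attribute `excluded` (number of points
#'   below the floor).
#' @export
mre <- function(truth, pred, floor = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  if (is.null(floor)) floor <- 1e-3 * max(abs(truth))
  keep <- abs(truth) >= floor
  if (!any(keep)) stop("mre: all points below the magnitude floor")
  out <- 100 * mean(sqrt((truth[keep] - pred[keep])^2 / truth[keep]^2))
  attr(out, "excluded") <- sum(!keep)
  out
}

# Scalarize a target matrix for the error functionals: velocity fields are
# reduced to their magnitude |V| (default) or scored per component.
scalarize_target <- function(x, mode = c("magnitude", "component")) {
  mode <- match.arg(mode)
  x <- rbind(x)
  if (ncol(x) == 1) return(as.numeric(x))
  if (mode == "magnitude") vec_norm(x) else as.numeric(x)
}

#' Evaluate a trained network on a test set
#'
#' Predicts every test pair, scalarizes velocity targets to `|V|`, and
#' computes NMAE and MRE per model on (a) all query points (`whole`) and
#' (b) sac-labelled points (`aneurysm`), then aggregates mean and standard
#' deviation across the test models.
#'
#' @param trained a `trained_model` from [train_network()].
#' @param test_set a `hemo_dataset` of the same variant.
#' @param mode velocity scalarization mode, `"magnitude"` (default) or
#'   `"component"`.
#' @return object of class `error_report`: `per_model` data frame and
#'   `summary` data frame (mean, sd per region x metric).
#' @export
evaluate_network <- function(trained, test_set, mode = "magnitude") {
  stopifnot(inherits(test_set, "hemo_dataset"))
  if (!identical(trained$variant, test_set$variant))
    stop("evaluate_network: variant mismatch (",
         paste(trained$variant, collapse = "/"), " vs ",
         paste(test_set$variant, collapse = "/"), ")")
  rows <- lapply(seq_along(test_set$pairs), function(i) {
    pair <- test_set$pairs[[i]]
    pred <- predict_network(trained, pair$model_cloud, pair$query_cloud)
    t_all <- scalarize_target(pair$target, mode)
    p_all <- scalarize_target(pred, mode)
    sac <- pair$region == "aneurysm_sac"
    if (identical(mode, "component")) sac <- rep(sac, ncol(rbind(pair$target)))
    one <- function(region, t, p) {
      m <- mre(t, p)
      data.frame(model = i, model_type = pair$params$model_type,
                 region = region, nmae = nmae(t, p), mre = as.numeric(m),
                 mre_excluded = attr(m, "excluded"))
    }
    rbind(one("whole", t_all, p_all),
          if (any(sac)) one("aneurysm", t_all[sac], p_all[sac]))
  })
  per_model <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(nmae, mre) ~ region, per_model, function(x)
    c(mean = mean(x), sd = stats::sd(x)))
  summary <- data.frame(region = agg$region,
                        nmae_mean = agg$nmae[, "mean"], nmae_sd = agg$nmae[, "sd"],
                        mre_mean = agg$mre[, "mean"], mre_sd = agg$mre[, "sd"])
  structure(list(per_model = per_model, summary = summary,
                 variant = test_set$variant, mode = mode),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report [%s]: %d test models\n",
              paste(x$variant, collapse = "/"),
              length(unique(x$per_model$model))))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s NMAE %5.2f +/- %4.2f %%   MRE %5.2f +/- %4.2f %%\n",
                s$region[i], s$nmae_mean[i], s$nmae_sd[i],
                s$mre_mean[i], s$mre_sd[i]))
  invisible(x)
}

#' Write an error report to JSON
#'
#' @param report an `error_report`.
#' @param path output file.
#' @export
write_error_report <- function(report, path) {
  jsonlite::write_json(
    list(variant = report$variant, mode = report$mode,
         summary = report$summary, per_model = report$per_model),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
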