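#' Calibrate LIE scaling parameters against experimental affinities
#'
#' Solves the no-intercept least-squares problem
#'
#'   minimize  sum_i (dG_exp_i - alpha * dV_vdw_i - beta * dV_ele_i)^2
#'
#' over the ligands present in both inputs, via the 2x2 normal equations.
#' There is no intercept: the LIE estimator passes through the origin by
#' construction. Ligands without an experimental affinity are excluded.
#'
#' @param deltas Data frame with `ligand_id`, `dV_vdw`, `dV_ele`.
#' @param exps Data frame with `ligand_id`, `dG_exp` (e.g. from
#'   [experimental_affinities()]).
#' @return A [lie_parameters()] with `source = "fitted"`, carrying the
#'   fitted ligand ids as attribute `ligand_ids`.
#' @export
fit_lie_parameters <- function(deltas, exps) {
  stopifnot(is.data.frame(deltas), is.data.frame(exps))
  m <- merge(deltas[, c("ligand_id", "dV_vdw", "dV_ele")],
             exps[!is.na(exps$dG_exp), c("ligand_id", "dG_exp")],
             by = "ligand_id")
  if (nrow(m) < 2L)
    stop("insufficient data: need >= 2 ligands with both energies and ",
         "experimental affinities, got ", nrow(m))
  X <- cbind(vdw = m$dV_vdw, ele = m$dV_ele)
  G <- crossprod(X)
  if (kappa(G, exact = TRUE) > 1e12)
    stop("collinearity error: normal matrix is numerically singular")
  ab <- solve(G, crossprod(X, m$dG_exp))
  p <- lie_parameters(ab[1L], ab[2L], source = "fitted")
  attr(p, "ligand_ids") <- m$ligand_id
  p
}

#' Squared Pearson correlation between predictions and observations
#'
#' The coefficient of determination reported for predicted-versus-observed
#' regressions. Being a squared correlation it is invariant to affine
#' transformations of either argument (including sign flips); it measures
#' linear association, not absolute agreement.
#'
#' @param pred,obs Paired numeric vectors, length >= 3.
#' @return Scalar in `[0, 1]`.
#' @export
coefficient_of_determination <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3L) stop("need >= 3 paired finite values")
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0)
    stop("undefined r^2: zero variance in predictions or observations")
  stats::cor(pred[ok], obs[ok])^2
}

#' Full calibration of the two LIE models
#'
#' Builds model-1 predictions (literature `alpha = 0.181`, per-ligand beta
#' via [assign_beta()]) and model-2 predictions (parameters fitted by
#' [fit_lie_parameters()]) for the ligands with experimental affinities,
#' and reports both coefficients of determination.
#'
#' @param deltas Delta table (`ligand_id`, `dV_vdw`, `dV_ele`, optional
#'   sems).
#' @param ligands Ligand descriptor table.
#' @param exps Experimental affinities; default computed from `ligands` at
#'   `temperature`.
#' @param temperature Temperature (K) for the Ki conversion.
#' @return A `lie_calibration`: list with `alpha`, `beta`, `r2_model1`,
#'   `r2_model2`, `n_ligands`, and a `points` data frame (`ligand_id`,
#'   `dV_vdw`, `dV_ele`, `pred_model1`, `pred_model2`, `dG_exp`,
#'   `residual_model2`).
#' @export
calibrate_lie <- function(deltas, ligands, exps = NULL,
                          temperature = 298.15) {
  if (is.null(exps)) exps <- experimental_affinities(ligands, temperature)
  fitted <- fit_lie_parameters(deltas, exps)
  m <- merge(deltas, exps[, c("ligand_id", "dG_exp")], by = "ligand_id")
  m <- m[match(attr(fitted, "ligand_ids"), m$ligand_id), ]
  m1 <- lie_table(m, ligands = ligands)            # literature scheme
  m2 <- lie_table(m, params = fitted)              # fitted scheme
  points <- data.frame(
    ligand_id = m$ligand_id, dV_vdw = m$dV_vdw, dV_ele = m$dV_ele,
    pred_model1 = m1$dG, pred_model2 = m2$dG, dG_exp = m$dG_exp,
    residual_model2 = m$dG_exp - m2$dG, stringsAsFactors = FALSE)
  structure(
    list(alpha = fitted$alpha, beta = fitted$beta,
         r2_model1 = coefficient_of_determination(points$pred_model1,
                                                  points$dG_exp),
         r2_model2 = coefficient_of_determination(points$pred_model2,
                                                  points$dG_exp),
         n_ligands = nrow(points), points = points),
    class = "lie_calibration"
  )
}

#' @export
print.lie_calibration <- function(x, ...) {
  cat(sprintf("<lie_calibration> %d ligands: alpha = %.3f, beta = %.3f\n",
              x$n_ligands, x$alpha, x$beta))
  cat(sprintf("  r^2 model 1 (literature) = %.3f; model 2 (fitted) = %.3f\n",
              x$r2_model1, x$r2_model2))
  invisible(x)
}

#' Leave-one-out cross-validation of the fitted LIE parameters
#'
#' Refits (alpha, beta) with each ligand held out in turn and predicts the
#' held-out binding free energy with the refit parameters.
#'
#' @inheritParams fit_lie_parameters
#' @return List with `predictions` (data frame `ligand_id`, `dG_exp`,
#'   `dG_loo`, `alpha`, `beta`) and `loo_rmse`.
#' @export
leave_one_out <- function(deltas, exps) {
  m <- merge(deltas[, c("ligand_id", "dV_vdw", "dV_ele")],
             exps[!is.na(exps$dG_exp), c("ligand_id", "dG_exp")],
             by = "ligand_id")
  if (nrow(m) < 3L)
    stop("insufficient data: leave-one-out needs >= 3 ligands")
  preds <- lapply(seq_len(nrow(m)), function(i) {
    p <- fit_lie_parameters(m[-i, ], m[-i, ])
    data.frame(ligand_id = m$ligand_id[i], dG_exp = m$dG_exp[i],
               dG_loo = p$alpha * m$dV_vdw[i] + p$beta * m$dV_ele[i],
               alpha = p$alpha, beta = p$beta, stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  list(predictions = preds,
       loo_rmse = sqrt(mean((preds$dG_exp - preds$dG_loo)^2)))
}

#' Serialize a calibration to a JSON report
#'
#' @param calibration A `lie_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calibration, path) {
  stopifnot(inherits(calibration, "lie_calibration"))
  if (nrow(calibration$points) == 0L)
    stop("validation error: calibration has no prediction points")
  jsonlite::write_json(
    list(alpha = calibration$alpha, beta = calibration$beta,
         r2_model1 = calibration$r2_model1,
         r2_model2 = calibration$r2_model2,
         n_ligands = calibration$n_ligands,
         points = calibration$points),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibration report written by [write_calibration_report()]
#'
#' @param path Input path.
#' @return A `lie_calibration` equal (up to JSON numeric round-trip) to the
#'   one written.
#' @export
read_calibration_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = x$alpha, beta = x$beta, r2_model1 = x$r2_model1,
         r2_model2 = x$r2_model2, n_ligands = x$n_ligands,
         points = as.data.frame(x$points)),
    class = "lie_calibration"
  )
}
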