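#' Named parameter presets
#'
#' Parameter bundles for the worked examples the package reproduces or
#' documents:
#' \describe{
#'   \item{fig4-triangle}{Equilateral-triangle / Kanizsa demonstration:
#'     `sigma0 = 0.1`, `alpha = 0.0853`, `t1 = 0`, `t2 = 0.75`.  The
#'     output threshold `t3 = 0.2` and the 12-orientation Gabor grid are
#'     package defaults for this demonstration (the AND-type output is
#'     near zero away from matching arrangements, so a low threshold
#'     suffices); no surround suppression, no geometric invariance.}
#'   \item{keyword-3.1}{Handwritten keyword spotting: `t1 = 0.1`,
#'     `t2 = 0.75`, `t3 = 0.1`, `sigma0 = 0.67`, `alpha = 0.1`.}
#'   \item{shoes-3.2}{Object spotting in cluttered indoor scenes:
#'     Gabor bank with `lambda = 4` and 16 orientations thresholded at
#'     `t1 = 0.3`, isotropic surround suppression on, `sigma0 = 0.1`,
#'     `alpha = 0.67`, `t3 = 0.1`, concentric configuration radii in
#'     steps of 4 px, reflection invariance with scales
#'     `{3/4, 1, 5/4}` and rotations `{-pi/8, 0, pi/8}`, keeping the two
#'     strongest detections per image.}
#' }
#'
#' @param name Preset name.
#' @return A list of parameter values (fields: `lambda`,
#'   `n_orientations`, `t1`, `t2`, `t3`, `sigma0`, `alpha`,
#'   `suppression`, `radii`, `psi_set`, `upsilon_set`, `reflect`,
#'   `top_k`).
#' @export
preset <- function(name = c("fig4-triangle", "keyword-3.1", "shoes-3.2")) {
  name <- match.arg(name)
  base <- list(lambda = 4, n_orientations = 12, t1 = 0, t2 = 0.75,
               t3 = 0, sigma0 = 0.1, alpha = 0.0853, suppression = 0,
               radii = seq(0, 12, by = 4), psi_set = 0, upsilon_set = 1,
               reflect = FALSE, top_k = NULL)
  switch(name,
    "fig4-triangle" = modifyList(base, list(t3 = 0.2)),
    "keyword-3.1" = modifyList(base, list(
      n_orientations = 16, t1 = 0.1, t3 = 0.1, sigma0 = 0.67,
      alpha = 0.1)),
    "shoes-3.2" = modifyList(base, list(
      n_orientations = 16, t1 = 0.3, t3 = 0.1, sigma0 = 0.1,
      alpha = 0.67, suppression = 1,
      psi_set = c(-pi / 8, 0, pi / 8), upsilon_set = c(3 / 4, 1, 5 / 4),
      reflect = TRUE, top_k = 2)))
}
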