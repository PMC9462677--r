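#' Calibrate the homogeneous disc modulus against a force target
#'
#' The intervertebral discs are modelled as one homogeneous isotropic
#' material (Poisson ratio 0.1 by default) whose modulus cannot be
#' derived from CT. It is calibrated so that the axial reaction at the
#' fixed base, under the prescribed pilot motion, matches the
#' experimentally measured force: the root of
#' `|axial reaction(E_disc)| - target` is found by bisection with
#' secant acceleration, stopping when the relative force mismatch is
#' at most `rel_tol` (default 0.1%).
#'
#' The global stiffness is linear in the disc modulus, so the bone and
#' unit-disc stiffness are assembled once and recombined per iteration;
#' each iteration still re-solves the full linear system.
#'
#' @param mesh a [tet_mesh()] with bone materials mapped and disc
#'   element sets named `disc*`.
#' @param bcs a [boundary_conditions()] with a prescribed pilot motion.
#' @param target_force target axial force magnitude (N); defaults to
#'   `bcs$target_force`.
#' @param bracket initial modulus bracket (MPa), default `c(0.1, 100)`.
#' @param nu_disc disc Poisson ratio (default 0.1).
#' @param rel_tol relative force tolerance (default 0.001 = 0.1%).
#' @param max_iter iteration cap (default 50).
#' @return list with `E_disc` (MPa), `force` (achieved axial force
#'   magnitude, N), `rel_diff`, `iterations`, `log` (tibble: iteration,
#'   E_disc, force, rel_diff), `solution` (the final [fe_solve()]
#'   result) and `mesh` (with disc materials set).
#' @export
calibrate_disc_modulus <- function(mesh, bcs, target_force = NULL,
                                   bracket = c(0.1, 100),
                                   nu_disc = 0.1, rel_tol = 0.001,
                                   max_iter = 50) {
  if (is.null(target_force)) target_force <- bcs$target_force
  if (is.null(target_force) || !is.finite(target_force) ||
      target_force <= 0)
    rlang::abort("a positive target force is required (an axial reaction of exactly zero is unattainable under a nonzero prescribed motion)",
                 class = "spinefe_bracket_error")
  if (length(bracket) != 2 || any(bracket <= 0) ||
      bracket[1] >= bracket[2])
    stop_input("`bracket` must be positive and ordered")
  disc_sets <- disc_set_names(mesh)
  if (length(disc_sets) == 0)
    stop_input("mesh has no `disc*` element sets")
  disc_idx <- which(element_in_sets(mesh, disc_sets))
  bone_idx <- setdiff(seq_len(nrow(mesh$elements)), disc_idx)
  K_bone <- fe_assemble(mesh, elements = bone_idx)
  K_disc1 <- fe_assemble(mesh, elements = disc_idx, E = 1,
                         nu = nu_disc)
  log <- tibble::tibble(iteration = integer(), E_disc = numeric(),
                        force = numeric(), rel_diff = numeric())
  it <- 0L
  last_sol <- NULL
  f_of <- function(E) {
    it <<- it + 1L
    sol <- fe_solve(mesh, bcs, K = K_bone + E * K_disc1)
    last_sol <<- sol
    f <- abs(sol$axial_force)
    log <<- dplyr::bind_rows(log, tibble::tibble(
      iteration = it, E_disc = E, force = f,
      rel_diff = abs(f - target_force) / target_force))
    f - target_force
  }
  a <- bracket[1]; b <- bracket[2]
  fa <- f_of(a); fb <- f_of(b)
  if (fa * fb > 0)
    rlang::abort(sprintf(
      "target force %.4g N is outside the bracket range [%.4g, %.4g] N",
      target_force, fa + target_force, fb + target_force),
      class = "spinefe_bracket_error")
  if (fa >= fb)
    rlang::abort("axial reaction is not increasing across the bracket endpoints",
                 class = "spinefe_contract_error")
  E <- a; fE <- fa
  for (k in seq_len(max_iter)) {
    if (abs(fE) / target_force <= rel_tol && k > 1) break
    # secant proposal, midpoint fallback when outside the bracket
    E_sec <- if (fb != fa) b - fb * (b - a) / (fb - fa) else NA_real_
    E <- if (is.finite(E_sec) && E_sec > a && E_sec < b) E_sec
         else (a + b) / 2
    fE <- f_of(E)
    if (abs(fE) / target_force <= rel_tol) break
    if (fE < 0) { a <- E; fa <- fE } else { b <- E; fb <- fE }
  }
  rel <- abs(fE) / target_force
  if (rel > rel_tol)
    rlang::abort(sprintf(
      "calibration did not reach the %.3g%% force criterion in %d iterations (last %.3g%%)",
      100 * rel_tol, max_iter, 100 * rel),
      class = "spinefe_convergence_error")
  mesh$E[disc_idx] <- E
  mesh$nu[disc_idx] <- nu_disc
  list(E_disc = E, force = abs(last_sol$axial_force), rel_diff = rel,
       iterations = it, log = log, solution = last_sol, mesh = mesh)
}

#' Write the calibration iteration log
#' @param calibration result of [calibrate_disc_modulus()].
#' @param path CSV output path.
#' @export
write_calibration_log <- function(calibration, path) {
  readr::write_csv(calibration$log, path)
  invisible(path)
}
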