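# Shared fixtures, built once per test run (mesh construction is cheap but
# the 642-vertex template is reused by many tests).

fixture_env <- new.env(parent = emptyenv())

rbc_fixture <- function() {
  if (is.null(fixture_env$rbc))
    fixture_env$rbc <- make_rbc_template(cell_template_spec())
  fixture_env$rbc
}

rbc782_fixture <- function() {
  if (is.null(fixture_env$rbc782))
    fixture_env$rbc782 <-
      make_rbc_template(cell_template_spec(diameter = 7.82))
  fixture_env$rbc782
}

patch_fixture <- function() {
  if (is.null(fixture_env$patch)) fixture_env$patch <- make_patch(0.5)
  fixture_env$patch
}

# small closed irregular mesh for gradient checks (fast)
blob_fixture <- function() {
  if (is.null(fixture_env$blob))
    fixture_env$blob <- make_plt_template(c(1, 0.9, 0.6), 1L)
  fixture_env$blob
}

# deterministic perturbed positions
perturbed <- function(mesh, amplitude, seed = 1) {
  set.seed(seed)
  mesh$vertices + amplitude *
    matrix(stats::rnorm(length(mesh$vertices)), ncol = 3L)
}

random_rotation <- function(seed = 4) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}
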