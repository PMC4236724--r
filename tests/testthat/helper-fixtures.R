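# Reference fixtures shared across test files.

ref_context <- function() cellular_context()            # 116,000 cells, 1 mL
ab_baseline_context <- function() cellular_context(n_cells = 67000)

# Totals implied by the reference per-cell endowments (nM)
REF_TBP <- 1.4036
REF_TR <- 2.5868e-3

# Independent quadratic oracle for a single binder: the bound complex is the
# smaller root of x^2 - (T1 + TB + Kd) x + T1 * TB = 0.
quadratic_complex <- function(total_ligand, total_binder, kd) {
  b <- total_ligand + total_binder + kd
  (b - sqrt(b^2 - 4 * total_ligand * total_binder)) / 2
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
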