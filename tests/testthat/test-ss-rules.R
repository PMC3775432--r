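# Convenience: an annotated_seq with hand-chosen properties, bypassing the
# residue table (the scan only consumes q, h and the hydropathy class).
synthetic_annotation <- function(q, h, philic) {
  structure(list(residues = rep("A", length(q)), q = q, h = h,
                 hydropathy = ifelse(philic, "hydrophilic", "hydrophobic"),
                 pH = 7, threshold = -3.3),
            class = "annotated_seq")
}

test_that("scan brackets open at hydrophilic residues and close within six neighbours", {
  # all-hydrophobic: no trigger
  a <- synthetic_annotation(rep(0, 8), rep(2, 8), rep(FALSE, 8))
  expect_length(open_helix_brackets(a), 0L)

  # hydrophilic at 1 and 4 -> one bracket with 2 intervening residues
  ph <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  a <- synthetic_annotation(rep(0, 6), c(-4, 2, 2, -4, 2, 2), ph)
  b <- open_helix_brackets(a)
  expect_length(b, 1L)
  expect_equal(b[[1]]$start, 1L)
  expect_equal(b[[1]]$end, 4L)
  expect_equal(b[[1]]$n_intervening, 2L)
  expect_equal(b[[1]]$end - b[[1]]$start - 1L, b[[1]]$n_intervening)

  # next hydrophilic residue eight positions away: no bracket, region skipped
  ph <- rep(FALSE, 10); ph[c(1, 9)] <- TRUE
  a <- synthetic_annotation(rep(0, 10), ifelse(ph, -4, 2), ph)
  expect_length(open_helix_brackets(a), 0L)

  # scanning resumes at the closing residue: triggers at 1, 3, 5 chain up
  ph <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  a <- synthetic_annotation(rep(0, 5), ifelse(ph, -4, 2), ph)
  b <- open_helix_brackets(a)
  expect_equal(vapply(b, `[[`, 1L, "start"), c(1L, 3L))
})

test_that("helix rule cases fire and miss as encoded", {
  rules <- load_helix_rules()
  mkb <- function(q, h) {
    structure(list(kind = "helix", start = 1L, end = length(q) + 2L,
                   n_intervening = length(q), q = q, h = h,
                   sum_q = sum(q), prod_q = if (length(q)) prod(q) else NA,
                   sum_h = sum(h)), class = "scan_bracket")
  }
  # n=1: small positive net charge with positive product
  expect_equal(evaluate_helix_bracket(mkb(0.1, 1), rules), "helix")
  # boundary: sum_q exactly 0 or 0.2 is outside the open interval
  expect_equal(evaluate_helix_bracket(mkb(0.0, 1), rules), "none")
  expect_equal(evaluate_helix_bracket(mkb(0.2, 1), rules), "none")
  # strongly charged single intervening residue matches no case
  expect_equal(evaluate_helix_bracket(mkb(-1, 1), rules), "none")
  # n=1 with large negative hydropathy but no charge support
  expect_equal(evaluate_helix_bracket(mkb(0.1, -100), rules), "helix") # case 1 still
  expect_equal(evaluate_helix_bracket(mkb(-0.1, -100), rules), "none")
  # n=2 falls back to the n=1 case
  expect_equal(evaluate_helix_bracket(mkb(c(0.05, 0.05), c(1, 1)), rules), "helix")
  # n=3: balanced charge plus strongly negative hydropathy sum
  expect_equal(evaluate_helix_bracket(mkb(c(0, 0.1, 0), c(-3, -3, -3)), rules), "helix")
  expect_equal(evaluate_helix_bracket(mkb(c(0, 0.1, 0), c(-3, -3, 3)), rules), "none")
  # n=5: all intervening charges positive
  expect_equal(evaluate_helix_bracket(mkb(rep(0.05, 5), rep(1, 5)), rules), "helix")
  # n=0 brackets never classify helix
  expect_equal(evaluate_helix_bracket(mkb(numeric(0), numeric(0)), rules), "none")
})

test_that("beta bracket enumeration walks unstructured windows left to right", {
  a <- synthetic_annotation(rep(0, 5), rep(1, 5), rep(FALSE, 5))
  expect_length(scan_beta_brackets(a, rep("H", 5)), 0L)
  b <- scan_beta_brackets(a, rep("C", 5))
  expect_length(b, 1L)
  expect_equal(c(b[[1]]$start, b[[1]]$end), c(1L, 5L))

  a6 <- synthetic_annotation(rep(0, 6), rep(1, 6), rep(FALSE, 6))
  b6 <- scan_beta_brackets(a6, rep("C", 6))
  expect_equal(vapply(b6, `[[`, 1L, "start"), c(1L, 2L))
})

test_that("beta inequalities are strict at both boundaries", {
  mkbeta <- function(sum_abs_q, sum_h) {
    structure(list(kind = "beta", start = 1L, end = 5L,
                   sum_abs_q = sum_abs_q, sum_h = sum_h),
              class = "scan_bracket")
  }
  expect_equal(evaluate_beta_bracket(mkbeta(0.1, 0.15)), "sheet")
  expect_equal(evaluate_beta_bracket(mkbeta(0.5, 0.2)), "none")  # diff exactly 0.3
  expect_equal(evaluate_beta_bracket(mkbeta(0.0, 0.1)), "none")  # sum_h exactly 0.1
  expect_equal(evaluate_beta_bracket(mkbeta(2.0, 0.5)), "none")  # diff 1.5 >= 0.3
})

test_that("the literal two-residue hydropathy summation variant is selectable", {
  # strongly hydrophobic head, hydrophilic tail: the full-bracket sum fails
  # the sheet test, the literal head-only sum passes it
  a <- synthetic_annotation(rep(0, 5), c(2, 2, -4, -4, -4), rep(FALSE, 5))
  full <- scan_beta_brackets(a, rep("C", 5), h_mode = "bracket")[[1]]
  head2 <- scan_beta_brackets(a, rep("C", 5), h_mode = "literal")[[1]]
  expect_equal(evaluate_beta_bracket(full), "none")
  expect_equal(evaluate_beta_bracket(head2), "sheet")
})

test_that("prediction labels cover the sequence, tile regions and are idempotent", {
  rules <- load_helix_rules()
  props <- aa_properties()
  set.seed(11)
  for (rep in 1:25) {
    s <- generate_fixture(sample(5:40, 1), "random", seed = rep)
    a <- annotate_sequence(s, pH = 7, props = props)
    p <- predict_secondary(a, rules)
    expect_length(p$labels, nchar(s))
    expect_true(all(p$labels %in% c("H", "E", "C")))
    # regions tile exactly the non-C labels, without overlap
    covered <- rep(FALSE, nchar(s))
    for (g in seq_len(nrow(p$regions))) {
      idx <- p$regions$start[g]:p$regions$end[g]
      expect_false(any(covered[idx]))
      covered[idx] <- TRUE
      expect_true(all(p$labels[idx] == p$regions$kind[g]))
    }
    expect_equal(covered, p$labels != "C")
    # idempotence: re-running the pure function changes nothing
    expect_identical(predict_secondary(a, rules), p)
  }
})

test_that("helix regions begin only at hydrophilic trigger residues", {
  props <- aa_properties()
  seqs <- c(lapply(1:10, function(s) generate_fixture(30, "random", seed = s)),
            lapply(c(7, 12, 21), function(n) generate_fixture(n, "helix_former")))
  n_h <- 0L
  for (s in seqs) {
    a <- annotate_sequence(s, pH = 7, props = props)
    p <- predict_secondary(a)
    for (g in which(p$regions$kind == "H")) {
      n_h <- n_h + 1L
      expect_equal(a$hydropathy[p$regions$start[g]], "hydrophilic")
    }
  }
  expect_gte(n_h, 3L)   # the helix formers guarantee helix regions to check
})

test_that("negative charge added to an intervening residue never turns a non-helix into a helix", {
  rules <- load_helix_rules()
  mkb <- function(q, h) {
    structure(list(kind = "helix", start = 1L, end = 3L, n_intervening = 1L,
                   q = q, h = h, sum_q = sum(q), prod_q = prod(q),
                   sum_h = sum(h)), class = "scan_bracket")
  }
  # mutating the intervening residue to a strongly charged one (|q| >= 0.9)
  # blocks the helix for every bracket on the grid; positive strong charges
  # are exempt only where the literal large-positive-charge rule row
  # (q1 > 0.9 with sum_h < -0.3) can fire
  for (h1 in seq(-8, 8, by = 0.5)) {
    for (qmut in c(-1, -0.95, -0.9))
      expect_equal(evaluate_helix_bracket(mkb(qmut, h1), rules), "none",
                   info = sprintf("q=%.2f h=%.1f", qmut, h1))
    if (h1 >= -0.3) {
      for (qmut in c(0.95, 1))
        expect_equal(evaluate_helix_bracket(mkb(qmut, h1), rules), "none",
                     info = sprintf("q=%.2f h=%.1f", qmut, h1))
    }
  }
})

test_that("label/region conversion validates input", {
  expect_error(labels_to_regions("HXC"), "labels")
  r <- labels_to_regions("CHHHCCEEEEEC")
  expect_equal(r$start, c(2L, 7L))
  expect_equal(r$end, c(4L, 11L))
  expect_equal(r$kind, c("H", "E"))
})
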