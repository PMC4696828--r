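toy_ranking <- function() {
  values <- matrix(c(-0.9, -0.5, 0.1, 0.3,
                     -0.2, -0.8, 0.4, -0.1), 4, 2,
                   dimnames = list(c("A", "B", "C", "D"), c("m1", "m2")))
  to_ranking(score_matrix(values, "toy", "ASC_SIGNED"))
}

test_that("extract_topk returns the k best per miRNA with name tie-breaks", {
  rk <- toy_ranking()
  top2 <- extract_topk(rk, 2)
  expect_equal(nrow(top2), 4)
  expect_equal(top2$mRNA[top2$miRNA == "m1"], c("A", "B"))
  expect_equal(top2$mRNA[top2$miRNA == "m2"], c("B", "A"))
  # k = N returns everything
  expect_equal(nrow(extract_topk(rk, 4)), 8)
  expect_error(extract_topk(rk, 5), "between 1 and")
  expect_error(extract_topk(rk, 0), "between 1 and")

  # tie across the k boundary: lexicographically smaller mRNA included
  tied <- score_matrix(matrix(c(1, 2, 2), 3, 1,
                              dimnames = list(c("C", "B", "A"), "m1")),
                       "toy", "ASC_SIGNED")
  top <- extract_topk(to_ranking(tied), 2)
  expect_equal(top$mRNA, c("C", "A"))
})

test_that("confirmed validation counts set intersections", {
  rk <- toy_ranking()
  truth <- ground_truth(c("m1", "m2", "m2"), c("B", "D", "C"))
  rep_ <- validate_confirmed(rk, 2, truth)
  per <- tidy(rep_)
  expect_equal(per$confirmed[per$miRNA == "m1"], 1)
  expect_equal(per$confirmed[per$miRNA == "m2"], 0)
  expect_equal(rep_$total, 1)

  # empty truth and all-covering truth
  expect_equal(validate_confirmed(rk, 2, ground_truth("zz", "yy"))$total, 0)
  full <- ground_truth(rep(c("m1", "m2"), each = 4),
                       rep(c("A", "B", "C", "D"), 2))
  expect_equal(validate_confirmed(rk, 3, full)$total, 6)
})

test_that("perturbation validation applies the strict |LFC| > threshold rule", {
  rk <- toy_ranking()
  pert <- perturbation_table(
    miRNA = c("m1", "m1", "m1"),
    gene = c("A", "B", "C"),
    lfc = c(1.0, -1.5, 2.0))
  rep_ <- validate_perturbation(rk, 2, pert, lfc_threshold = 1.0)
  per <- tidy(rep_)
  # A at exactly 1.0 is NOT a target; B at -1.5 is
  expect_equal(per$confirmed[per$miRNA == "m1"], 1)
  # m2 has no perturbation records: uncovered, 0 confirmed
  expect_equal(per$confirmed[per$miRNA == "m2"], 0)
  expect_equal(rep_$uncovered, "m2")
})

test_that("validation totals match a brute-force intersection oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:10) {
    n_mir <- sample(2:4, 1); n_rna <- sample(5:12, 1)
    sm <- score_matrix(
      matrix(rnorm(n_rna * n_mir), n_rna, n_mir,
             dimnames = list(sprintf("G%02d", 1:n_rna),
                             sprintf("m%d", 1:n_mir))),
      "rand", "ASC_SIGNED")
    rk <- to_ranking(sm)
    k <- sample(seq_len(n_rna), 1)
    pairs_n <- sample(5:20, 1)
    truth <- ground_truth(sprintf("m%d", sample(n_mir, pairs_n, TRUE)),
                          sprintf("G%02d", sample(n_rna, pairs_n, TRUE)))
    got <- validate_confirmed(rk, k, truth)$total
    # oracle: literal double loop over miRNAs and truth pairs
    want <- 0
    for (m in sprintf("m%d", 1:n_mir)) {
      v <- sort(unclass(sm)[, m])
      top <- names(v)[seq_len(k)]
      for (i in seq_len(nrow(truth))) {
        if (truth$miRNA[i] == m && truth$mRNA[i] %in% top) {
          want <- want + 1
        }
      }
    }
    expect_equal(got, want)
  }
})

test_that("compare_methods reproduces hand-computed ranking scores", {
  mk_report <- function(counts, label) {
    per <- tibble::tibble(miRNA = names(counts), confirmed = counts,
                          targets = list(character()))
    mirlens:::new_validation(per, 2, label, "confirmed")
  }
  # 2 methods, 1 miRNA, counts (5, 3): scores (2, 1)
  cmp <- compare_methods(list(a = mk_report(c(m1 = 5), "a"),
                              b = mk_report(c(m1 = 3), "b")))
  expect_equal(cmp$ranking_score, c(2, 1))

  # equal counts everywhere: full symmetry, all 1.5 per miRNA
  cmp2 <- compare_methods(list(a = mk_report(c(m1 = 2, m2 = 1), "a"),
                               b = mk_report(c(m1 = 2, m2 = 1), "b")))
  expect_equal(cmp2$ranking_score, c(3, 3))

  # 3 methods, 2 miRNAs, m2 drops method 1 to zero: only m1 retained
  cmp3 <- compare_methods(list(
    a = mk_report(c(m1 = 4, m2 = 0), "a"),
    b = mk_report(c(m1 = 4, m2 = 2), "b"),
    c = mk_report(c(m1 = 1, m2 = 2), "c")))
  expect_equal(attr(cmp3, "retained"), "m1")
  expect_equal(cmp3$ranking_score, c(2.5, 2.5, 1))

  # no retained miRNA: explicit notice, NA scores
  expect_message(
    cmp4 <- compare_methods(list(a = mk_report(c(m1 = 0), "a"),
                                 b = mk_report(c(m1 = 1), "b"))),
    "no miRNA")
  expect_true(all(is.na(cmp4$ranking_score)))
})

test_that("comparison scores are order-invariant and conserve the point total", {
  set.seed(55)
  M <- 4
  mk_report <- function(counts, label) {
    per <- tibble::tibble(miRNA = names(counts), confirmed = counts,
                          targets = list(character()))
    mirlens:::new_validation(per, 3, label, "confirmed")
  }
  counts <- replicate(M, setNames(sample(0:5, 6, TRUE),
                                  sprintf("m%d", 1:6)), simplify = FALSE)
  reports <- lapply(seq_len(M), function(i)
    mk_report(counts[[i]], paste0("meth", i)))
  names(reports) <- paste0("meth", 1:M)
  cmp <- compare_methods(reports)
  retained <- attr(cmp, "retained")
  if (length(retained) > 0) {
    expect_equal(sum(cmp$ranking_score),
                 length(retained) * M * (M + 1) / 2)
  }
  perm <- c(3, 1, 4, 2)
  cmp_perm <- compare_methods(reports[perm])
  expect_equal(cmp_perm$ranking_score[match(cmp$method, cmp_perm$method)],
               cmp$ranking_score)
})

test_that("a tiny threshold makes perturbation validation equal confirmed validation", {
  rk <- toy_ranking()
  pert <- perturbation_table(c("m1", "m2"), c("B", "A"), c(0.6, -0.9))
  as_truth <- ground_truth(pert$miRNA, pert$gene)
  v_pert <- validate_perturbation(rk, 2, pert, lfc_threshold = 1e-9)
  v_conf <- validate_confirmed(rk, 2, as_truth)
  expect_equal(v_pert$total, v_conf$total)
  expect_equal(tidy(v_pert)$confirmed, tidy(v_conf)$confirmed)
})
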