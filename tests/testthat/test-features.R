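fm_from_matrix <- function(m, ids = sprintf("c%02d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  dt50prob:::feature_matrix(m, ids, rep("external_table", ncol(m)))
}

test_that("min-max scaling follows the fit/apply contract", {
  m <- cbind(c(2, 4, 6), c(5, 5, 5))
  fm <- fit_scale(fm_from_matrix(m))
  expect_equal(unname(fm$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(fm$values[, 2]), c(0, 0, 0))  # constant column -> 0

  # test-time values outside the training range are not clipped
  q <- apply_scale(fm_from_matrix(matrix(c(8, 1), 2, 1)), fm$scaler_state[1, ])
  expect_equal(unname(q$values[, 1]), c(1.5, -0.25))

  expect_error(apply_scale(fm_from_matrix(m), NULL), "not been fitted")
  expect_error(select_features(fm_from_matrix(m)), "scaled matrix")
})

test_that("feature selection drops low variance and correlated clusters", {
  set.seed(42)
  n <- 200
  base <- runif(n)
  m <- cbind(base,                 # cluster of three rank-identical columns
             2 * base + 1,
             -base,                # |spearman| = 1 via negation
             rep(0.5, n),          # constant: variance filter
             matrix(runif(n * 5), n))  # 5 independent columns
  fm <- fit_scale(fm_from_matrix(m))
  sel <- select_features(fm)
  rep <- attr(sel, "selection")

  expect_false(rep$retained[4])            # constant dropped
  expect_true(is.na(rep$cluster_id[4]))
  expect_equal(sum(rep$retained[1:3]), 1)  # one survivor of the |r|=1 cluster
  expect_equal(sum(rep$retained[5:9]), 5)  # independent columns all survive
  expect_equal(ncol(sel$values), 6)

  # brute-force post-conditions: pairwise |spearman| < 0.99, variance >= 0.02
  r <- cor(sel$values, method = "spearman")
  expect_lt(max(abs(r[upper.tri(r)])), 0.99)
  expect_true(all(apply(sel$values, 2, var) >= 0.02))

  # idempotence: selecting from the selected matrix changes nothing
  sel2 <- select_features(sel)
  expect_equal(sel2$values, sel$values)

  # everything filtered away is a clear error
  expect_error(select_features(fit_scale(fm_from_matrix(cbind(rep(1, 5))))),
               "variance threshold")
})

test_that("featurization is deterministic and matches frozen fingerprints", {
  fm <- featurize(c("c1ccccc1", "c1ccccc1", "CCO"), feature_set_spec("maccs"))
  expect_equal(ncol(fm$values), 166)
  expect_true(all(fm$values %in% c(0, 1)))
  expect_equal(fm$values[1, ], fm$values[2, ])  # same SMILES -> same row
  # benzene MACCS keys (computed once with RDKit 2024.09, frozen):
  # 0-based bits 161, 162, 164 -> columns 162, 163, 165
  expect_equal(which(fm$values[1, ] == 1), c(162L, 163L, 165L),
               ignore_attr = TRUE)

  fp <- featurize(c("C", "CC"), feature_set_spec("path_fp_2048"))
  expect_equal(ncol(fp$values), 2048)
  a <- fp$values[1, ] == 1; b <- fp$values[2, ] == 1
  tan <- sum(a & b) / sum(a | b)
  expect_lt(tan, 1)  # methane and ethane differ on path fingerprints

  # multi-block featurization tags sources
  fb <- featurize("CCO", feature_set_spec(c("maccs", "avalon", "descriptors_2d")))
  expect_setequal(unique(fb$source), c("maccs", "avalon", "descriptors_2d"))
  expect_false(any(!is.finite(fb$values)))
})

test_that("the external descriptor table reader aligns by compound id", {
  ext <- tempfile(fileext = ".csv")
  write.csv(data.frame(compound_id = c("b", "a"), d1 = c(2, 1), d2 = c(20, 10)),
            ext, row.names = FALSE)
  recs <- list(compound_record("a", "CCO"), compound_record("b", "CCC"))
  fm <- featurize(recs, feature_set_spec("external_table", external_path = ext))
  expect_equal(unname(fm$values[, "ext_d1"]), c(1, 2))  # reordered to records

  recs2 <- c(recs, list(compound_record("zz", "CCN")))
  expect_error(
    featurize(recs2, feature_set_spec("external_table", external_path = ext)),
    "zz")
})

test_that("tanimoto kNN distance matches a brute-force oracle", {
  train <- c("CCO", "CCCO", "c1ccccc1", "c1ccccc1O", "CC(=O)O")
  expect_equal(tanimoto_knn_distance("CCO", train, k = 1), 0)
  expect_error(tanimoto_knn_distance("CCO", character(0)), "empty training")
  expect_error(tanimoto_knn_distance("CCO", train, k = 9), "k exceeds")

  # brute-force check of the k-largest averaging, k = 3
  queries <- c("CCCCO", "c1ccncc1")
  d <- tanimoto_knn_distance(queries, train, k = 3)
  bits <- function(s) sort(unlist(
    dt50prob:::chem_batch("fingerprint", s,
                          list(fp_type = "morgan", n_bits = 2048))[[1]]$on_bits))
  for (i in seq_along(queries)) {
    q <- bits(queries[i])
    sims <- vapply(train, function(t) {
      tb <- bits(t)
      length(intersect(q, tb)) / length(union(q, tb))
    }, numeric(1))
    expect_equal(d[i], 1 - mean(sort(sims, decreasing = TRUE)[1:3]))
  }
  expect_true(all(d >= 0 & d <= 1))
})
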