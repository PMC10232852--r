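# Full-enumeration Shapley oracle: the subset-weight formula
# phi_i = sum over S not containing i of |S|!(M-|S|-1)!/M! (v(S+i) - v(S)),
# with v(S) the mean model output when S's coordinates come from x and the
# rest from a background row.  Written independently of the package code.
oracle_shapley <- function(f, x, background, groups) {
  M <- length(groups)
  v <- function(sel_groups) {
    vals <- vapply(seq_len(nrow(background)), function(b) {
      z <- background[b, ]
      for (g in sel_groups) z[groups[[g]]] <- x[groups[[g]]]
      f(matrix(z, nrow = 1))
    }, 0)
    mean(vals)
  }
  phi <- numeric(M)
  for (i in seq_len(M)) {
    others <- setdiff(seq_len(M), i)
    for (size in 0:length(others)) {
      subsets <- if (size == 0) list(integer(0))
                 else asplit(utils::combn(others, size), 2)
      w <- factorial(size) * factorial(M - size - 1) / factorial(M)
      for (S in subsets) {
        phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
      }
    }
  }
  phi
}

test_that("exact Shapley values match full subset enumeration", {
  withr::with_seed(4, {
    for (M in c(3L, 5L, 8L)) {
      W <- rnorm(M)
      V <- matrix(rnorm(M * M, sd = 0.3), M, M)
      f <- function(rows) {
        # nonlinear surrogate: sigmoid of a quadratic form
        1 / (1 + exp(-(rows %*% W + rowSums((rows %*% V) * rows))))
      }
      x <- rnorm(M)
      bg <- matrix(rnorm(3 * M), 3, M)
      res <- shapley_values(f, x, bg, method = "exact")
      expect_equal(res$phi, oracle_shapley(f, x, bg, as.list(seq_len(M))),
                   tolerance = 1e-6, label = sprintf("M=%d", M))
      expect_lt(abs(res$residual), 1e-6)
      expect_equal(res$f_x, as.numeric(f(matrix(x, nrow = 1))),
                   tolerance = 1e-10)
      expect_equal(res$phi0, mean(f(bg)), tolerance = 1e-10)
    }
  })
})

test_that("binary-feature surrogates are attributed exactly too", {
  withr::with_seed(9, {
    M <- 6L
    f <- function(rows) 0.1 + 0.8 * (rows[, 1] * rows[, 2]) + 0.05 * rows[, 5]
    x <- rep(1, M)
    bg <- matrix(rbinom(4 * M, 1, 0.5), 4, M)
    res <- shapley_values(f, x, bg, method = "exact")
    expect_equal(res$phi, oracle_shapley(f, x, bg, as.list(seq_len(M))),
                 tolerance = 1e-10)
    expect_equal(res$phi[6], 0)  # untouched feature: null player
  })
})

test_that("sampling mode keeps additivity exactly and approximates exact", {
  withr::with_seed(10, {
    M <- 7L
    W <- rnorm(M)
    f <- function(rows) as.numeric(1 / (1 + exp(-rows %*% W)))
    x <- rnorm(M)
    bg <- matrix(rnorm(5 * M), 5, M)
    exact <- shapley_values(f, x, bg, method = "exact")
    samp <- shapley_values(f, x, bg, method = "sampling", nsim = 400,
                           seed = 1)
    expect_lt(abs(samp$residual), 1e-10)
    expect_equal(samp$phi, exact$phi, tolerance = 0.05)
    samp2 <- shapley_values(f, x, bg, method = "sampling", nsim = 400,
                            seed = 1)
    expect_identical(samp$phi, samp2$phi)  # seeded determinism
  })
})

test_that("sequence attribution gives the constant center zero weight", {
  # deterministic toy predictor over 41-nt windows: depends on positions
  # 18 (G) and 25 (A) only
  pred <- function(batch) {
    0.2 + 0.6 * batch$x[, 18, "G"] + 0.15 * batch$x[, 25, "A"]
  }
  rec <- generate_dataset(synthetic_config(n_pos = 6, n_neg = 6,
                                           plant_prob = 1, seed = 44))
  x <- rec[1, , drop = FALSE]
  bg <- rec[7:12, , drop = FALSE]
  attr_ <- shap_attributions(pred, x, bg, method = "sampling", nsim = 30,
                             seed = 2)
  expect_equal(dim(attr_$phi), c(41L, 4L))
  expect_lt(abs(attr_$residual), 1e-10)
  imp <- per_base_importance(attr_)
  expect_length(imp, 41L)
  expect_equal(imp[21], 0)           # center U is constant: null player
  expect_gt(imp[18], 0.1)            # the informative planted G
  expect_equal(sum(abs(imp[c(1:10, 30:41)])), 0, tolerance = 1e-10)
})

test_that("all-zero attributions give a zero importance vector", {
  attr_ <- structure(list(phi = matrix(0, 41, 4,
                                       dimnames = list(NULL, c("A", "C", "G", "U"))),
                          phi0 = 0.5, f_x = 0.5, residual = 0,
                          seq = random_windows(1, seed = 3), id = "s"),
                     class = "attribution_matrix")
  expect_equal(per_base_importance(attr_), rep(0, 41))
})

test_that("normalization scales to [-0.25, 0.25] without changing signs", {
  withr::with_seed(15, {
    phi <- matrix(0, 41, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
    seqs <- random_windows(1, seed = 16)
    obs <- match(strsplit(seqs, "")[[1]], c("A", "C", "G", "U"))
    phi[cbind(1:41, obs)] <- rnorm(41, sd = 0.2)
    phi[21, ] <- 0
    phi[5, obs[5]] <- 0.5  # forces max |phi| = 0.5
    a <- structure(list(phi = phi, phi0 = 0.4, f_x = 0.6, residual = 0,
                        seq = seqs, id = "s1"),
                   class = "attribution_matrix")
    norm <- normalize_and_accumulate(list(a))
    expect_equal(max(abs(norm$scaled[[1]])), 0.25)
    expect_equal(norm$scaled[[1]], phi * 0.5, tolerance = 1e-12)
    expect_identical(sign(norm$scaled[[1]]), sign(phi))
    # accumulation restricted to observed bases equals the scaled matrix here
    expect_equal(norm$accumulated, phi * 0.5, tolerance = 1e-12,
                 ignore_attr = TRUE)

    zero <- a
    zero$phi <- phi * 0
    nz <- normalize_and_accumulate(list(zero))
    expect_equal(max(abs(nz$scaled[[1]])), 0)
  })
  expect_error(normalize_and_accumulate(list()), "no attributions")
})

test_that("attribution tables export in position x base layout", {
  phi <- matrix(rnorm(41 * 4, sd = 0.1), 41, 4,
                dimnames = list(NULL, c("A", "C", "G", "U")))
  a <- structure(list(phi = phi, phi0 = 0.5, f_x = 0.5, residual = 0,
                      seq = random_windows(1, seed = 8), id = "s"),
                 class = "attribution_matrix")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attribution_table(a, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(colnames(tab), c("position", "A", "C", "G", "U"))
  expect_equal(nrow(tab), 41L)
  expect_equal(as.matrix(tab[, -1]), phi, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("class separation scores cleanly separated and shuffled labels", {
  withr::with_seed(30, {
    coords <- rbind(matrix(rnorm(100, mean = 0, sd = 0.05), 50, 2),
                    matrix(rnorm(100, mean = 5, sd = 0.05), 50, 2))
    labels <- rep(c(0, 1), each = 50)
    expect_gt(class_separation(coords, labels), 0.95)
    expect_lt(abs(class_separation(coords, sample(labels))), 0.2)
  })
  expect_error(class_separation(matrix(0, 4, 2), rep(1, 4)), "two classes")
})

test_that("umap projection embeds to 2-D deterministically", {
  withr::with_seed(40, {
    act <- structure(list(layer_name = "toy",
                          matrix = rbind(matrix(rnorm(600, 0, 0.3), 30, 20),
                                         matrix(rnorm(600, 4, 0.3), 30, 20)),
                          ids = sprintf("s%02d", 1:60),
                          labels = rep(c(0L, 1L), each = 30)),
                     class = "layer_activation")
  })
  emb <- umap_project(act, n_neighbors = 10, seed = 7)
  expect_equal(dim(emb$coords), c(60L, 2L))
  expect_true(all(is.finite(emb$coords)))
  emb2 <- umap_project(act, n_neighbors = 10, seed = 7)
  expect_identical(emb$coords, emb2$coords)
  # two well-separated clusters stay separated in the embedding
  expect_gt(class_separation(emb), 0.5)
  expect_error(umap_project(act, n_neighbors = 100), "n_neighbors")
})
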