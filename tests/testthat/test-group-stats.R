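test_that("identical groups give a null omnibus and no significant pairs", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r <- kruskal_dunn(v, g)
  expect_lt(r$omnibus_stat, 0.1)
  expect_gt(r$omnibus_p, 0.9)
  expect_true(all(r$pairwise$p_adj > 0.05))
  expect_equal(unname(r$letters), c("a", "a"))
})

test_that("all-tied data are flagged degenerate with p = 1", {
  r <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(r$degenerate)
  expect_equal(r$omnibus_p, 1)
  expect_equal(unname(r$letters), c("a", "a", "a"))
})

test_that("Dunn raw p ordering matches the exhaustive permutation oracle", {
  v <- c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  g <- rep(c("a", "b", "c"), each = 3)
  dn <- dunn_test(v, g, adjust = "none")
  # permutation p for each pair from full enumeration (1680 assignments)
  pp <- mapply(function(a, b) perm_rank_p(v, g, a, b),
               dn$group1, dn$group2)
  # the extreme pair (a, c) has the smallest p on both routes
  ac <- which(dn$group1 == "a" & dn$group2 == "c")
  expect_equal(which.min(dn$p_raw), ac)
  expect_equal(unname(which.min(pp)), ac)
  # ordering of all pairs agrees between Dunn z and the oracle
  expect_equal(order(dn$p_raw), order(pp))
})

test_that("rank statistics are invariant to location shifts", {
  set.seed(3)
  v <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  r1 <- kruskal_dunn(v, g)
  r2 <- kruskal_dunn(v + 100, g)
  expect_equal(r1$omnibus_stat, r2$omnibus_stat)
  expect_equal(r1$pairwise$z, r2$pairwise$z)
  expect_equal(r1$letters, r2$letters)
})

test_that("Dunn variance uses the pooled tie correction", {
  # with heavy ties the tie-corrected z must differ from the uncorrected one
  v <- c(1, 1, 2, 2, 2, 3, 3, 9, 9, 9)
  g <- rep(c("a", "b"), each = 5)
  dn <- dunn_test(v, g, adjust = "none")
  r <- rank(v)
  N <- length(v)
  ties <- table(v)
  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) * (2 / 5)
  z_hand <- (mean(r[g == "a"]) - mean(r[g == "b"])) / sqrt(sig2)
  expect_equal(dn$z, z_hand, tolerance = 1e-12)
})

test_that("compact letters satisfy the display axioms on canonical cases", {
  lev <- c("A", "B", "C")
  none <- matrix(FALSE, 3, 3, dimnames = list(lev, lev))
  expect_equal(unname(compact_letters(none)), c("a", "a", "a"))
  all_sig <- matrix(TRUE, 3, 3, dimnames = list(lev, lev))
  diag(all_sig) <- FALSE
  expect_equal(sort(unname(compact_letters(all_sig))), c("a", "b", "c"))
  # chain A != C, A = B, B = C
  chain <- none
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  cl <- compact_letters(chain)
  expect_equal(unname(cl), c("a", "ab", "b"))
  expect_true(letters_satisfy_axioms(cl, chain))
  expect_error(compact_letters(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)),
               "symmetric")
})

test_that("compact letters satisfy the axioms on random significance matrices", {
  set.seed(19)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    lev <- LETTERS[1:k]
    sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        sig[i, j] <- sig[j, i] <- runif(1) < 0.4
      }
    }
    cl <- compact_letters(sig)
    expect_true(letters_satisfy_axioms(cl, sig),
                info = paste("matrix rep", rep))
  }
})

test_that("paired Wilcoxon matches exact enumeration and is symmetric", {
  x <- c(2, 4, 6, 8, 10, 12)
  y <- x - c(1, 2, 3, 4, 5, 6) / 2
  r <- paired_test(x, y)   # all 6 differences positive
  expect_equal(r$p, 2 / 2^6)
  expect_equal(r$n, 6)
  r_swap <- paired_test(y, x)
  expect_equal(r_swap$p, r$p)
  deg <- paired_test(x, x)
  expect_true(deg$degenerate)
  expect_error(paired_test(1:3, 1:4), "equal length")
})

test_that("Spearman correlation matches hand rank arithmetic", {
  expect_equal(rank_correlation(1:5, 1:5 * 2)$R, 1)
  # sum d^2 = 4 -> 1 - 6*4/(5*24) = 0.8
  expect_equal(rank_correlation(1:5, c(2, 1, 4, 3, 5))$R, 0.8)
  # sum d^2 = 6 -> 1 - 6*6/(5*24) = 0.7
  expect_equal(rank_correlation(1:5, c(3, 1, 2, 4, 5))$R, 0.7)
  a <- rnorm(10)
  b <- rnorm(10)
  expect_equal(rank_correlation(a, b)$R, rank_correlation(b, a)$R)
  expect_error(rank_correlation(1:5, rep(1, 5)), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})
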