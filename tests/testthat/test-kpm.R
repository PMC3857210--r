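std_expr <- function(m) {
  e <- expr_from_matrix(m, scale = "standardized")
  e
}

test_that("indicator entries flag case values outside the reference band", {
  # reference samples with mean 0 and sd 1 per gene, by construction
  ref <- sprintf("A%02d", 1:10)
  cas <- c("B01", "B02")
  m <- matrix(0, nrow = 3, ncol = 12, dimnames = list(paste0("g", 1:3), c(ref, cas)))
  set.seed(2)
  refvals <- t(apply(matrix(rnorm(30), nrow = 3), 1, function(x) (x - mean(x)) / sd(x)))
  m[, ref] <- refvals
  m["g1", cas] <- c(0, 3)      # at the mean vs z = 3
  m["g2", cas] <- c(1.9, -2.1)
  m["g3", cas] <- c(0.5, -0.5)
  grp <- tibble::tibble(sample = c(ref, cas), group = rep(c("A", "B"), c(10, 2)))
  ind <- build_indicator_matrix(std_expr(m), grp)
  im <- mat_of(ind)
  expect_equal(unname(im["g1", ]), c(0, 1))
  expect_equal(unname(im["g2", ]), c(0, 1))
  expect_equal(unname(im["g3", ]), c(0, 0))
  expect_equal(attr(ind, "alpha"), 0.05)

  mz <- m
  mz["g3", ref] <- 0  # zero reference variance
  expect_warning(indz <- build_indicator_matrix(std_expr(mz), grp), "g3")
  expect_equal(unname(mat_of(indz)["g3", ]), c(0, 0))

  expect_error(build_indicator_matrix(expr_from_matrix(abs(m) + 1), grp),
               "standardize")
})

test_that("null case samples activate at close to the nominal rate", {
  set.seed(31)
  n_genes <- 50
  n_ref <- 182
  n_case <- 48
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("A%03d", 1:n_ref), sprintf("B%03d", 1:n_case))
  log2m <- matrix(rnorm(n_genes * (n_ref + n_case), 8, 1), nrow = n_genes,
                  dimnames = list(genes, samples))
  grp <- tibble::tibble(sample = samples,
                        group = rep(c("A", "B"), c(n_ref, n_case)))
  ind <- build_indicator_matrix(standardize_samples(expr_from_matrix(2^log2m)), grp)
  rate <- mean(mat_of(ind))
  n_entries <- n_genes * n_case
  se <- sqrt(0.05 * 0.95 / n_entries)
  expect_gt(n_entries, 2000)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("node activity counts case exceptions against the L budget", {
  m <- matrix(0L, nrow = 3, ncol = 48,
              dimnames = list(c("full", "partial", "none"), sprintf("c%02d", 1:48)))
  m["full", ] <- 1L
  m["partial", 1:30] <- 1L
  ind <- tibble::as_tibble(m, rownames = "gene")
  a0 <- node_activity(ind, 0)
  expect_true(a0$active[a0$gene == "full"])
  expect_false(a0$active[a0$gene == "partial"])
  expect_equal(a0$n_exceptions[a0$gene == "partial"], 18)
  expect_false(node_activity(ind, 17)$active[2])
  expect_true(node_activity(ind, 18)$active[2])
  expect_true(all(node_activity(ind, 48)$active))
})

test_that("the exact solver handles the canonical path instances", {
  path3 <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  all_active <- tibble::as_tibble(
    matrix(1L, 3, 4, dimnames = list(c("a", "b", "c"), paste0("c", 1:4))),
    rownames = "gene")
  sol <- solve_ines_exact(path3, all_active, K = 8, L = 0)
  expect_equal(sol$size[1], 3)
  expect_equal(sol$nodes[[1]], c("a", "b", "c"))

  # a - x - b with x inactive: K = 0 gives the singletons, K = 1 bridges
  axb <- tibble::tibble(from = c("a", "x"), to = c("x", "b"))
  ind <- tibble::as_tibble(
    matrix(c(1L, 1L, 0L, 1L, 1L, 0L), nrow = 3,
           dimnames = list(c("a", "b", "x"), c("c1", "c2"))),
    rownames = "gene")
  k0 <- solve_ines_exact(axb, ind, K = 0, L = 0)
  expect_equal(k0$size, c(1L, 1L))
  expect_equal(sort(unlist(k0$nodes)), c("a", "b"))
  k1 <- solve_ines_exact(axb, ind, K = 1, L = 0)
  expect_equal(k1$size[1], 3)
  expect_equal(k1$exception_nodes[[1]], "x")

  # no active nodes: the result is empty whatever K allows
  none <- ind
  none[c("c1", "c2")] <- 0L
  expect_equal(nrow(solve_ines_exact(axb, none, K = 0, L = 0)), 0)
  expect_equal(nrow(solve_ines_exact(axb, none, K = 8, L = 0)), 0)

  big <- tibble::tibble(from = sprintf("n%02d", 1:30), to = sprintf("n%02d", c(2:30, 1)))
  expect_error(solve_ines_exact(big, all_active, K = 0, L = 0), "greedy")
})

test_that("the exact solver agrees with full connected-subset enumeration", {
  for (seed in 1:30) {
    set.seed(seed + 500)
    inst <- random_kpm_instance(n_nodes = sample(6:10, 1), n_cases = 6,
                                seed = seed + 500)
    K <- sample(0:2, 1)
    L <- sample(0:3, 1)
    got <- solve_ines_exact(inst$edges, inst$ind, K = K, L = L, top_n = 10)
    want <- brute_kpm(inst$edges, inst$ind, K = K, L = L, top_n = 10)
    expect_equal(got$nodes, want)
  }
})

test_that("greedy solutions are valid, deterministic, and bounded by the optimum", {
  for (seed in 1:15) {
    inst <- random_kpm_instance(n_nodes = 10, n_cases = 6, seed = seed + 900)
    K <- seed %% 3
    L <- seed %% 4
    greedy <- solve_ines_greedy(inst$edges, inst$ind, K = K, L = L, seed = seed)
    exact <- solve_ines_exact(inst$edges, inst$ind, K = K, L = L, top_n = 1)
    if (nrow(greedy)) {
      for (i in seq_len(nrow(greedy))) {
        expect_true(validate_kpm_solution(greedy$nodes[[i]], inst$edges,
                                          inst$ind, K = K, L = L))
      }
      expect_lte(greedy$size[1], exact$size[1])
    } else {
      expect_equal(nrow(exact), 0)
    }
    again <- solve_ines_greedy(inst$edges, inst$ind, K = K, L = L, seed = seed)
    expect_identical(greedy$nodes, again$nodes)
  }
})

test_that("greedy search completes a fully active clique", {
  genes <- paste0("q", 1:6)
  pairs <- t(combn(genes, 2))
  clique <- tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  ind <- tibble::as_tibble(
    matrix(1L, 6, 3, dimnames = list(genes, paste0("c", 1:3))),
    rownames = "gene")
  sol <- solve_ines_greedy(clique, ind, K = 0, L = 0, seed = 4)
  expect_equal(sol$size[1], 6)
})

test_that("solution size grows monotonically in K and in L", {
  inst <- random_kpm_instance(n_nodes = 10, n_cases = 8, seed = 77, p_active = 0.4)
  best <- function(K, L) {
    s <- solve_ines_exact(inst$edges, inst$ind, K = K, L = L, top_n = 1)
    if (nrow(s)) s$size[1] else 0L
  }
  for (L in c(0, 2, 4)) {
    sizes <- vapply(0:3, best, integer(1), L = L)
    expect_true(all(diff(sizes) >= 0))
  }
  for (K in 0:2) {
    sizes <- vapply(c(0, 2, 4, 6, 8), function(L) best(K, L), integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the minimal L reaching a target size is found and monotone", {
  m <- matrix(0L, nrow = 3, ncol = 48,
              dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:48)))
  m["a", 1:30] <- 1L   # misses 18 cases
  m["b", 1:40] <- 1L   # misses 8
  m["c", ] <- 1L
  ind <- tibble::as_tibble(m, rownames = "gene")
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))

  expect_equal(min_L_for_size(path, ind, K = 0, target_size = 1), 0)  # c active at L=0
  expect_equal(min_L_for_size(path, ind, K = 0, target_size = 3), 18)
  single <- tibble::tibble(from = "a", to = "b")
  expect_equal(min_L_for_size(single, ind, K = 0, target_size = 1), 8)

  # monotone in the target
  answers <- vapply(1:3, function(t) min_L_for_size(path, ind, K = 0, target_size = t),
                    integer(1))
  expect_true(all(diff(answers) >= 0))

  expect_message(res <- min_L_for_size(path, ind, K = 0, target_size = 4),
                 "unattainable")
  expect_true(is.na(res))
})
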