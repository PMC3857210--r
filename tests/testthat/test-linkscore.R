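test_that("link scores equal the sum of endpoint log2 fold changes", {
  nodes <- tibble::tibble(gene = c("a", "b", "c"),
                          mean_ref = c(1, 1, 4),
                          mean_case = c(2, 2, 1))
  an <- structure(list(nodes = nodes,
                       edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))),
                  class = "annotated_network")
  ls <- compute_link_scores(an)
  expect_equal(ls$link_score[1], 2)            # log2(2*2 / 1*1)
  expect_equal(ls$link_score[2], 1 - 2)        # log2(2/1) + log2(1/4)

  same <- an
  same$nodes$mean_case <- same$nodes$mean_ref
  expect_equal(compute_link_scores(same)$link_score, c(0, 0))

  bad <- an
  bad$nodes$mean_ref[2] <- 0
  expect_error(compute_link_scores(bad), "b")
})

test_that("link scores match a brute-force oracle, antisymmetrically and scale-free", {
  for (seed in 1:5) {
    an <- random_annotated(n_nodes = 12, n_edges = 50, seed = seed)
    ls <- compute_link_scores(an)
    oracle <- vapply(seq_len(nrow(an$edges)), function(k) {
      mi <- an$nodes[an$nodes$gene == an$edges$from[k], ]
      mj <- an$nodes[an$nodes$gene == an$edges$to[k], ]
      log2((mi$mean_case * mj$mean_case) / (mi$mean_ref * mj$mean_ref))
    }, numeric(1))
    expect_equal(ls$link_score, oracle, tolerance = 1e-12)

    swapped <- an
    swapped$nodes$mean_ref <- an$nodes$mean_case
    swapped$nodes$mean_case <- an$nodes$mean_ref
    expect_equal(compute_link_scores(swapped)$link_score, -ls$link_score)

    scaled <- an
    scaled$nodes$mean_ref <- an$nodes$mean_ref * 17.3
    scaled$nodes$mean_case <- an$nodes$mean_case * 17.3
    expect_equal(compute_link_scores(scaled)$link_score, ls$link_score,
                 tolerance = 1e-12)
  }
})

test_that("top-k selection takes the extreme scores with deterministic ties", {
  ls <- tibble::tibble(from = c("a", "b", "c"), to = c("x", "y", "z"),
                       link_score = c(2, 0, -1))
  cs <- select_top_links(ls, k_up = 1, k_down = 1)
  expect_setequal(paste(cs$edges$from, cs$edges$to), c("a x", "c z"))
  expect_equal(cs$edges$direction[cs$edges$from == "a"], "up")

  empty <- select_top_links(ls, 0, 0)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)

  # tie on the score: canonical edge id decides, stably
  tie <- tibble::tibble(from = c("b", "a", "c"), to = c("q", "q", "q"),
                        link_score = c(1, 1, 1))
  got <- select_top_links(tie, k_up = 2, k_down = 0)
  expect_equal(sort(got$edges$from), c("a", "b"))

  expect_warning(select_top_links(ls, k_up = 5, k_down = 0), "clamping")
  sel <- suppressWarnings(select_top_links(ls, k_up = 5, k_down = 5))
  expect_equal(nrow(sel$edges), 2)  # only one positive and one negative edge
})

test_that("top-k selection equals exhaustive sort-and-slice", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:40, 1)
    ls <- tibble::tibble(from = sprintf("e%02da", seq_len(n)),
                         to = sprintf("e%02db", seq_len(n)),
                         link_score = sample(c(-3:3, runif(7, -2, 2)), n, replace = TRUE))
    k_up <- sample(0:4, 1)
    k_down <- sample(0:4, 1)
    cs <- suppressWarnings(select_top_links(ls, k_up, k_down))
    id <- paste(ls$from, ls$to)
    pos <- ls[ls$link_score > 0, ]
    neg <- ls[ls$link_score < 0, ]
    want_up <- head(pos[order(-pos$link_score, paste(pos$from, pos$to)), ], k_up)
    want_down <- head(neg[order(neg$link_score, paste(neg$from, neg$to)), ], k_down)
    got_up <- cs$edges[cs$edges$direction == "up", ]
    got_down <- cs$edges[cs$edges$direction == "down", ]
    expect_identical(paste(got_up$from, got_up$to), paste(want_up$from, want_up$to))
    expect_identical(paste(got_down$from, got_down$to), paste(want_down$from, want_down$to))
    expect_true(all(got_up$link_score > 0))
    expect_true(all(got_down$link_score < 0))
  }
})

test_that("group-label swap negates scores and mirrors the selection", {
  an <- random_annotated(10, 20, seed = 99)
  cs <- select_top_links(compute_link_scores(an), 3, 3)
  swapped <- an
  swapped$nodes$mean_ref <- an$nodes$mean_case
  swapped$nodes$mean_case <- an$nodes$mean_ref
  cs2 <- select_top_links(compute_link_scores(swapped), 3, 3)
  key <- function(e, d) sort(paste(e$from, e$to)[e$direction == d])
  expect_identical(key(cs$edges, "up"), key(cs2$edges, "down"))
  expect_identical(key(cs$edges, "down"), key(cs2$edges, "up"))
})

test_that("interaction activity shifts are detected and BH-adjusted", {
  set.seed(21)
  n <- 20
  genes <- c("u1", "u2", "n1", "n2")
  ref <- sprintf("A%02d", 1:n)
  cas <- sprintf("B%02d", 1:n)
  log2m <- matrix(rnorm(4 * 2 * n, 6, 0.3), nrow = 4,
                  dimnames = list(genes, c(ref, cas)))
  log2m[c("u1", "u2"), cas] <- log2m[c("u1", "u2"), cas] + 1  # 2-fold shift
  expr <- expr_from_matrix(2^log2m)
  grp <- tibble::tibble(sample = c(ref, cas), group = rep(c("A", "B"), each = n))
  edges <- tibble::tibble(from = c("u1", "n1"), to = c("u2", "n2"))
  res <- test_interaction_shifts(expr, grp, edges)
  expect_true(res$significant[1])
  expect_gt(res$estimate[1], 1.5)
  expect_false(res$significant[2])

  # against the direct t-test oracle on the per-sample log2 product
  a <- log2m["u1", ] + log2m["u2", ]
  tt <- t.test(a[cas], a[ref])
  expect_equal(res$p.value[1], tt$p.value)
  expect_equal(res$statistic[1], unname(tt$statistic))

  expect_error(test_interaction_shifts(expr, grp,
                                       tibble::tibble(from = "zz", to = "u1")),
               "absent")
})

test_that("permutation-symmetric input gives null interaction statistics", {
  # both groups observe the same multiset of activities, with nonzero spread
  m <- matrix(rep(c(4.001, 4.002, 4.001, 4.002), times = 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expr <- expr_from_matrix(m)
  grp <- tibble::tibble(sample = paste0("s", 1:4), group = c("A", "A", "B", "B"))
  res <- test_interaction_shifts(expr, grp, tibble::tibble(from = "g1", to = "g2"))
  expect_lt(abs(res$statistic), 1e-8)
  expect_gt(res$p.value, 0.99)
})

test_that("gene-level testing reports the fraction significantly changed", {
  set.seed(5)
  n <- 15
  genes <- sprintf("g%03d", 1:100)
  ref <- sprintf("A%02d", 1:n)
  cas <- sprintf("B%02d", 1:n)
  log2m <- matrix(rnorm(100 * 2 * n, 7, 0.25), nrow = 100,
                  dimnames = list(genes, c(ref, cas)))
  grp <- tibble::tibble(sample = c(ref, cas), group = rep(c("A", "B"), each = n))

  null_res <- test_gene_de(expr_from_matrix(2^log2m), grp)
  expect_lte(fraction_significant(null_res), 0.1)  # BH under the null

  shifted <- log2m
  shifted[, cas] <- shifted[, cas] + 4 * 0.25
  full <- test_gene_de(expr_from_matrix(2^shifted), grp)
  expect_equal(fraction_significant(full), 1)

  one <- test_gene_de(expr_from_matrix(2^shifted), grp, genes = "g001")
  expect_true(fraction_significant(one) %in% c(0, 1))
})

test_that("components of a selected edge set match a BFS oracle", {
  cs <- list(edges = tibble::tibble(from = c("a", "c"), to = c("b", "d")))
  expect_equal(network_components(cs$edges), list(c("a", "b"), c("c", "d")))
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  expect_equal(network_components(path), list(c("a", "b", "c")))

  set.seed(13)
  genes <- sprintf("n%02d", 1:15)
  edges <- tibble::tibble(from = sample(genes, 20, TRUE),
                          to = sample(genes, 20, TRUE))
  edges <- edges[edges$from != edges$to, ]
  got <- network_components(edges)
  # plain BFS oracle
  nbr <- lapply(setNames(nm = unique(c(edges$from, edges$to))), function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  seen <- character(0)
  comps <- list()
  for (v in names(nbr)) {
    if (v %in% seen) next
    q <- v
    comp <- character(0)
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      q <- c(q, setdiff(nbr[[u]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps <- comps[order(-lengths(comps), vapply(comps, min, character(1)))]
  expect_equal(got, comps)
})

test_that("BH adjustment follows the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(p), rep(0.04, 4))
  set.seed(9)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})
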