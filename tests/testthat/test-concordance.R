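# recognized species maps and partitions are both expressed as named
# assignments over a small id universe

rec <- function(...) list(...)

test_that("a species-cluster bijection is perfect taxonomy throughout", {
  recognized <- rec(r1 = c("a", "b"), r2 = c("c", "d"), r3 = c("e"))
  part <- new_partition_for_test(
    c(a = 1, b = 1, c = 2, d = 2, e = 3))
  out <- classify_species(recognized, part)
  expect_true(all(out$category == "perfect_taxonomy"))
  expect_true(all(out$clusters_spanned == 1))
  expect_true(all(out$cohabitants == ""))
})

test_that("splits are classified pure or impure by cluster exclusivity", {
  # r split across two clusters that contain only r -> pure undersplit
  recognized <- rec(r = c("a", "b", "c"), s = c("d", "e"))
  pure <- new_partition_for_test(c(a = 1, b = 1, c = 2, d = 3, e = 3))
  out <- classify_species(recognized, pure)
  expect_equal(as.character(out$category[out$species == "r"]),
               "pure_undersplit")
  expect_equal(out$clusters_spanned[out$species == "r"], 2)

  # same split but one cluster also holds s -> impure undersplit
  impure <- new_partition_for_test(c(a = 1, b = 1, c = 2, d = 2, e = 3))
  out2 <- classify_species(recognized, impure)
  expect_equal(as.character(out2$category[out2$species == "r"]),
               "impure_undersplit")
  expect_equal(out2$cohabitants[out2$species == "r"], "s")
  # and s, split across clusters 2 and 3 with r in 2, is impure too
  expect_equal(as.character(out2$category[out2$species == "s"]),
               "impure_undersplit")
})

test_that("pooled species are oversplits, impure when a partner leaks", {
  recognized <- rec(r = c("a", "b"), s = c("c", "d"), t = c("e", "f"))
  pooled <- new_partition_for_test(
    c(a = 1, b = 1, c = 1, d = 1, e = 2, f = 2))
  out <- classify_species(recognized, pooled)
  expect_equal(as.character(out$category[out$species == "r"]),
               "pure_oversplit")
  expect_equal(as.character(out$category[out$species == "s"]),
               "pure_oversplit")
  expect_equal(as.character(out$category[out$species == "t"]),
               "perfect_taxonomy")

  # s leaks one member elsewhere: r becomes impure oversplit, s an impure
  # undersplit
  leaky <- new_partition_for_test(
    c(a = 1, b = 1, c = 1, d = 3, e = 2, f = 2))
  out2 <- classify_species(recognized, leaky)
  expect_equal(as.character(out2$category[out2$species == "r"]),
               "impure_oversplit")
  expect_equal(as.character(out2$category[out2$species == "s"]),
               "impure_undersplit")
})

test_that("classification is invariant to cluster relabeling", {
  set.seed(81)
  ids <- letters[1:8]
  for (i in 1:10) {
    sp <- sample(paste0("r", 1:3), 8, replace = TRUE)
    names(sp) <- ids
    if (length(unique(sp)) < 2) next
    cl <- sample(1:4, 8, replace = TRUE)
    p1 <- new_partition_for_test(stats::setNames(cl, ids))
    shuffled <- sample(10:20)[cl]
    p2 <- new_partition_for_test(stats::setNames(shuffled, ids))
    expect_equal(classify_species(sp, p1)$category,
                 classify_species(sp, p2)$category)
  }
})

test_that("refinements never oversplit and coarsenings never undersplit", {
  set.seed(82)
  ids <- letters[1:9]
  sp <- stats::setNames(rep(paste0("r", 1:3), each = 3), ids)
  # refinement: split each species into finer clusters
  refine <- new_partition_for_test(
    stats::setNames(c(1, 1, 2, 3, 4, 4, 5, 6, 7), ids))
  out <- classify_species(sp, refine)
  expect_false(any(grepl("oversplit", out$category)))
  # coarsening: merge whole species
  coarse <- new_partition_for_test(
    stats::setNames(c(1, 1, 1, 1, 1, 1, 2, 2, 2), ids))
  out2 <- classify_species(sp, coarse)
  expect_false(any(grepl("undersplit", out2$category)))
})

test_that("summary percentages and the delimited ratio use printed-report rounding", {
  cats <- rep(c("perfect_taxonomy", "pure_undersplit", "impure_undersplit",
                "impure_oversplit"), c(19, 23, 16, 8))
  records <- data.frame(species = paste0("sp", seq_along(cats)),
                        category = factor(cats,
                                          levels = barcodegap:::CONCORDANCE_CATEGORIES),
                        clusters_spanned = 1L, cohabitants = "")
  part <- new_partition_for_test(
    stats::setNames(seq_len(163), paste0("x", 1:163)))
  s <- summarize_concordance(records, part)
  expect_equal(unname(s$counts), c(19, 23, 16, 0, 8))
  expect_equal(unname(s$percentages), c(29, 35, 24, 0, 12))
  expect_equal(s$n_recognized, 66)
  expect_equal(s$delimited_ratio, 2.5)

  one <- data.frame(species = "r", category = factor("perfect_taxonomy",
                    levels = barcodegap:::CONCORDANCE_CATEGORIES),
                    clusters_spanned = 1L, cohabitants = "")
  p1 <- new_partition_for_test(c(a = 1))
  s1 <- summarize_concordance(one, p1)
  expect_equal(unname(s1$percentages), c(100, 0, 0, 0, 0))
})

test_that("classification errors on mismatched id sets", {
  recognized <- rec(r = c("a", "b"))
  part <- new_partition_for_test(c(a = 1, b = 1, c = 2))
  expect_error(classify_species(recognized, part), "different id sets")
})

test_that("the five categories are exhaustive and mutually exclusive", {
  # brute force: all set partitions of n ids against species labelings,
  # checked with independent per-category predicates
  set_partitions <- function(ids) {
    if (length(ids) == 1L) return(list(list(ids)))
    rest <- set_partitions(ids[-1])
    out <- list()
    for (p in rest) {
      for (k in seq_along(p)) {
        q <- p; q[[k]] <- c(ids[1], q[[k]])
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(list(ids[1]), p)
    }
    out
  }
  predicates <- function(members, clusters_of, recognized) {
    clusters <- unique(clusters_of[members])
    in_cl <- names(clusters_of)[clusters_of %in% clusters]
    exclusive <- all(vapply(clusters, function(cl) {
      all(names(clusters_of)[clusters_of == cl] %in% members)
    }, logical(1)))
    others <- setdiff(unique(unlist(lapply(recognized, function(m)
      if (any(m %in% in_cl)) m))), members)
    list(
      perfect = length(clusters) == 1 && exclusive &&
        setequal(in_cl, members),
      pure_under = length(clusters) >= 2 && exclusive,
      impure_under = length(clusters) >= 2 && !exclusive,
      pure_over = length(clusters) == 1 && length(others) > 0 &&
        all(others %in% in_cl),
      impure_over = length(clusters) == 1 && length(others) > 0 &&
        !all(others %in% in_cl))
  }
  ids <- letters[1:5]
  parts <- set_partitions(ids)
  set.seed(83)
  labelings <- c(
    lapply(1:6, function(i) stats::setNames(
      sample(paste0("r", 1:2), 5, replace = TRUE), ids)),
    lapply(1:6, function(i) stats::setNames(
      sample(paste0("r", 1:3), 5, replace = TRUE), ids)))
  labelings <- Filter(function(l) length(unique(l)) > 1, labelings)
  for (p in parts) {
    clusters_of <- stats::setNames(
      rep(seq_along(p), lengths(p)), unlist(p))
    part_obj <- new_partition_for_test(clusters_of)
    for (lab in labelings) {
      recognized <- split(names(lab), unname(lab))
      out <- classify_species(recognized, part_obj)
      for (r in names(recognized)) {
        pr <- predicates(recognized[[r]], clusters_of, recognized)
        flags <- unlist(pr)
        expect_equal(sum(flags), 1L)
        got <- as.character(out$category[out$species == r])
        want <- c(perfect = "perfect_taxonomy",
                  pure_under = "pure_undersplit",
                  impure_under = "impure_undersplit",
                  pure_over = "pure_oversplit",
                  impure_over = "impure_oversplit")[names(flags)[flags]]
        expect_equal(got, unname(want))
      }
    }
  }
})
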