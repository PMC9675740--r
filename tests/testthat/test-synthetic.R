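test_that("generate_truth is seed-deterministic and collision-free by construction", {
  a <- generate_truth(5, synonyms_per_record = 2, seed = 7)
  b <- generate_truth(5, synonyms_per_record = 2, seed = 7)
  expect_identical(a$registry, b$registry)
  c <- generate_truth(5, synonyms_per_record = 2, seed = 8)
  expect_false(identical(a$registry$prefix, c$registry$prefix))

  single <- generate_truth(1, synonyms_per_record = 0, seed = 1)
  expect_identical(nrow(single$registry), 1L)
  expect_identical(nrow(validate_registry(single$registry)), 0L)

  big <- generate_truth(200, synonyms_per_record = 3, seed = 1)
  expect_identical(nrow(validate_record(big$registry)), 0L)
  expect_identical(nrow(validate_registry(big$registry)), 0L)
  expect_s3_class(build_prefix_index(big$registry), "prefix_index")
})

test_that("perturb_profile rejects rates outside [0, 1]", {
  expect_s3_class(perturb_profile(), "perturb_profile")
  expect_error(perturb_profile(casing_rate = 1.2), class = "prefixkit_value_error")
  expect_error(perturb_profile(field_dropout = c(name = -0.1)),
               class = "prefixkit_value_error")
})

test_that("derive_dump respects the perturbation profile", {
  truth <- generate_truth(50, synonyms_per_record = 2, seed = 3)

  # identity profile: dump prefixes equal canonical prefixes verbatim
  plain <- derive_dump(truth, "r",
                       perturb_profile(0, 0, 0, 0, field_dropout = c(name = 0)), seed = 1)
  expect_setequal(plain$dump$external_prefix, truth$registry$prefix)
  expect_identical(nrow(plain$dump), 50L)

  # pure punctuation: every prefix differs from canonical yet norm_key-equal
  punct <- derive_dump(truth, "r",
                       perturb_profile(0, 1, 0, 0, field_dropout = c(name = 0)), seed = 1)
  expect_true(all(punct$dump$external_prefix != punct$planted$prefix[
    match(punct$dump$external_prefix, punct$planted$external_prefix)]))
  expect_identical(norm_key(punct$planted$external_prefix), norm_key(punct$planted$prefix))

  # novel rows: exact ceiling(novel_rate * n) count, disjoint from all truth keys
  novel <- derive_dump(truth, "r", perturb_profile(0, 0, 0, novel_rate = 0.2), seed = 9)
  is_novel <- !novel$dump$external_prefix %in% novel$planted$external_prefix
  expect_identical(sum(is_novel), 10L)
  truth_keys <- norm_key(unlist(c(truth$registry$prefix, truth$registry$synonyms)))
  expect_false(any(norm_key(novel$dump$external_prefix[is_novel]) %in% truth_keys))

  expect_identical(derive_dump(truth, "r", perturb_profile(), seed = 4)$dump,
                   derive_dump(truth, "r", perturb_profile(), seed = 4)$dump)
})

test_that("score_alignment computes precision and recall with boundary conventions", {
  truth <- generate_truth(10, seed = 2)
  ds <- derive_dump(truth, "r", perturb_profile(1, 1, 0, 0), seed = 2)
  res <- align(truth$registry, group_meta("r", 1L), ds$dump)
  perfect <- score_alignment(res, ds$planted)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$recall, 1)

  # empty result on a nonempty planted map: precision 1 by convention, recall 0
  empty_res <- align(truth$registry, group_meta("r", 3L), ds$dump[0, ])
  boundary <- score_alignment(empty_res, ds$planted)
  expect_identical(boundary$precision, 1)
  expect_identical(boundary$recall, 0)

  # hand count: one wrong of four emitted against four planted -> 0.75 / 0.75
  planted <- tibble::tibble(registry_key = "r", external_prefix = paste0("E", 1:4),
                            prefix = paste0("p", 1:4))
  res4 <- structure(list(new_mappings = tibble::tibble(
    prefix = c("p1", "p2", "p3", "WRONG"), registry_key = "r",
    external_prefix = paste0("E", 1:4), provenance = "automated"
  )), class = "alignment_result")
  hand <- score_alignment(res4, planted)
  expect_identical(hand$precision, 0.75)
  expect_identical(hand$recall, 0.75)
})

test_that("synonym swaps from the curated vocabulary keep recall at 1 and never corrupt precision", {
  truth <- generate_truth(60, synonyms_per_record = 2, seed = 21)
  meta <- group_meta("r", 2L)
  for (seed in 1:3) {
    ds <- derive_dump(truth, "r",
                      perturb_profile(casing_rate = 0.5, punctuation_rate = 0.5,
                                      synonym_swap_rate = 0.6, novel_rate = 0),
                      seed = seed)
    sc <- score_alignment(align(truth$registry, meta, ds$dump), ds$planted)
    expect_identical(sc$precision, 1)
    expect_identical(sc$recall, 1)
  }
})
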