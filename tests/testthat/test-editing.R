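dims7 <- structure(list(K = 7L, high = 1:3, low = 4:7), class = "bs_dims")

expand_all <- function(specs, dims = dims7) {
  combine_factor_tables(unlist(lapply(names(specs), function(nm) {
    lapply(alias_to_selectors(nm, specs[[nm]]), expand_selector, dims = dims)
  }), recursive = FALSE))
}

test_that("effect aliases expand to their BS features", {
  expect_equal(alias_to_selectors("shine", 2),
               list(list(freq = "H", amp = "H", sign = "P", strength = 2)))
  aging <- alias_to_selectors("aging", 3)
  expect_length(aging, 2)
  expect_equal(aging[[1]][c("freq", "amp", "sign")],
               list(freq = "H", amp = "L", sign = "A"))  # HLA
  expect_equal(aging[[2]][c("freq", "amp", "sign")],
               list(freq = "H", amp = "H", sign = "N"))  # HHN
  expect_equal(vapply(aging, `[[`, 0, "strength"), c(3, 3))

  # acronyms parse positionally
  expect_equal(alias_to_selectors("HHP", 2),
               list(list(freq = "H", amp = "H", sign = "P", strength = 2)))
  expect_error(alias_to_selectors("sparkle", 2), class = "bs_arg_error")
  expect_error(alias_to_selectors("shine", Inf), class = "bs_arg_error")
})

test_that("blemish compiles to the same factor table as rough plus stain", {
  expect_equal(expand_all(list(blemish = 3)),
               expand_all(list(rough = 3, stain = 3)))
})

test_that("selector expansion honours groups, wildcards and explicit indices", {
  # freq 'H' at K=7 is exactly freq = 1:3
  byname <- expand_selector(list(freq = "H", amp = "H", sign = "P",
                                 strength = 3), dims7)
  byidx <- expand_selector(list(freq = 1:3, amp = "H", sign = "P",
                                strength = 3), dims7)
  expect_equal(byname, byidx)

  # freq = 1:2, amp 'L', sign 'A' -> exactly four cells at the strength
  tab <- expand_selector(list(freq = 1:2, amp = "L", sign = "A",
                              strength = 4), dims7)
  m <- unclass(tab)
  expect_equal(sum(m == 4), 4L)
  expect_equal(m[1:2, c("LP", "LN")], matrix(4, 2, 2,
               dimnames = list(NULL, c("LP", "LN"))))
  expect_true(all(m[3:7, ] == 1) && all(m[1:2, c("HP", "HN")] == 1))

  # strength 1 is the identity table
  expect_true(all(unclass(expand_selector(list(freq = "A", amp = "A",
    sign = "A", strength = 1), dims7)) == 1))

  # 'L' accepted as a synonym for negative sign
  expect_equal(expand_selector(list(freq = "H", amp = "H", sign = "L",
                                    strength = 2), dims7),
               expand_selector(list(freq = "H", amp = "H", sign = "N",
                                    strength = 2), dims7))

  expect_error(expand_selector(list(freq = 8, amp = "H", sign = "P",
                                    strength = 2), dims7),
               class = "bs_arg_error")
})

test_that("factor tables combine commutatively and multiplicatively", {
  a <- expand_all(list(shine = 0.2, aging = 3))
  b <- expand_all(list(aging = 3, shine = 0.2))
  expect_equal(a, b)

  t1 <- expand_selector(list(freq = "H", amp = "H", sign = "P",
                             strength = 2), dims7)
  expect_equal(combine_factor_tables(list(t1, feature_factor_table(7))), t1)
  t2 <- expand_selector(list(freq = "H", amp = "H", sign = "P",
                             strength = 3), dims7)
  expect_equal(unclass(combine_factor_tables(list(t1, t2)))[1:3, "HP"],
               rep(6, 3))
  expect_error(combine_factor_tables(list(t1, feature_factor_table(5))),
               class = "bs_arg_error")
})

test_that("strength 1 returns the input bit-identically for every effect", {
  img <- make_glossy_surface(size = 96, seed = 51)$image
  for (e in c("shine", "spots", "rough", "stain", "blemish", "shadow",
              "aging", "HHP", "LLN"))
    expect_identical(modif(img, e, 1), img)
  expect_error(modif(img, character(0)), class = "bs_arg_error")
})

test_that("effect order never changes the output", {
  img <- make_spotted_surface(size = 96, seed = 52)$image
  ab <- modif(img, c("shine", "aging"), c(0.2, 3))
  ba <- modif(img, c("aging", "shine"), c(3, 0.2))
  expect_identical(ab, ba)
})

test_that("modif2 selectors reproduce the alias effects pixel for pixel", {
  img <- make_glossy_surface(size = 96, seed = 53)$image
  expect_identical(
    modif2(img, list(freq = "H", amp = "H", sign = "P", strength = 3)),
    modif(img, "shine", 3))
  # explicit high indices == 'H' (K = 5 at 96 px: high = 1:2)
  dims <- modif_dim(img)
  expect_identical(
    modif2(img, list(freq = dims$high, amp = "H", sign = "P", strength = 3)),
    modif2(img, list(freq = "H", amp = "H", sign = "P", strength = 3)))
  # feature acronym form
  expect_identical(modif2(img, list(feature = "HHP", strength = 3)),
                   modif(img, "shine", 3))
})

test_that("several selectors apply as one combined pass, not sequentially", {
  img <- make_spotted_surface(size = 96, seed = 54)$image
  joint <- modif2(img, list(
    list(freq = "H", amp = "H", sign = "N", strength = 2),
    list(freq = "H", amp = "L", sign = "P", strength = 1.5)))
  expect_identical(joint, modif(img, c("spots", "rough"), c(2, 1.5)))
  sequential <- modif(modif(img, "spots", 2), "rough", 1.5)
  expect_false(identical(joint, sequential))
})

test_that("mask blending is exact at its extremes and midpoint", {
  img <- make_glossy_surface(size = 96, seed = 55)$image
  edited <- modif(img, "shine", 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  expect_identical(blend_with_mask(img, edited, matrix(1, h, w)), edited)
  expect_identical(blend_with_mask(img, edited, matrix(0, h, w)), img)
  half <- blend_with_mask(img, edited, matrix(0.5, h, w))
  expect_lt(max(abs(half - (img + edited) / 2)), 1e-12)
  expect_error(blend_with_mask(img, edited, matrix(1, h, w + 1)),
               class = "bs_shape_error")
})

test_that("masked edits touch only the masked region", {
  img <- make_glossy_surface(size = 96, seed = 56)$image
  h <- dim(img)[1]; w <- dim(img)[2]
  mask <- matrix(0, h, w)
  mask[20:60, 10:50] <- 1
  unmasked <- modif(img, "shine", 3, max_size = NA)
  masked <- modif(img, "shine", 3, mask = mask, max_size = NA)
  inside <- array(rep(mask == 1, 3), dim(img))
  expect_identical(masked[!inside], img[!inside])
  expect_identical(masked[inside], unmasked[inside])
  expect_error(modif(img, "shine", 3, mask = matrix(1, h - 1, w)),
               class = "bs_shape_error")
})

test_that("editing preserves the chroma channels before gamut clipping", {
  img <- random_image(96, 96, seed = 57)  # saturated random chroma
  lab <- srgb_to_lab(img)
  tab <- expand_selector(list(freq = "A", amp = "A", sign = "A",
                              strength = 2.5), modif_dim(img))
  out <- edit_lab(lab, tab)
  expect_identical(out$a, lab$a)
  expect_identical(out$b, lab$b)
  expect_false(identical(out$L, lab$L))
})

test_that("shine and spots move fixture regions monotonically in strength", {
  glossy <- make_glossy_surface(size = 128, seed = 58)
  hi <- glossy$mask == 1
  mean_high_L <- vapply(c(0.5, 1, 2, 3), function(s)
    mean(srgb_to_lab(modif(glossy$image, "shine", s))$L[hi]), 0)
  expect_true(all(diff(mean_high_L) >= 0))
  # boosting shine strictly brightens the highlight region
  expect_gt(mean_high_L[4], mean(srgb_to_lab(glossy$image)$L[hi]))

  spotted <- make_spotted_surface(size = 128, seed = 59)
  sp <- spotted$mask == 1
  mean_spot_L <- vapply(c(0.5, 1, 2, 3), function(s)
    mean(srgb_to_lab(modif(spotted$image, "spots", s))$L[sp]), 0)
  expect_true(all(diff(mean_spot_L) <= 0))
})
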