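count_pat <- function(svg, pat) {
  sum(gregexpr(pat, svg, fixed = TRUE)[[1]] > 0)
}

test_that("layout places every person once with the right state counts", {
  t <- nf_table(34, 426, 2, 538)
  lay <- nf_layout(t)
  p <- lay$placements
  expect_equal(nrow(p), 1000)
  expect_equal(as.vector(table(p$state)[c("tp", "fp", "fn", "tn")]),
               c(34, 426, 2, 538))
  expect_equal(sum(p$at_risk), 460)
  expect_equal(sum(p$event), 36)
  expect_equal(anyDuplicated(p[, c("row", "col")]), 0L)

  # group-contiguous block order: events first within the at-risk block
  expect_true(all(p$state[1:34] == "tp"))
  expect_true(all(p$state[35:460] == "fp"))
  expect_true(all(p$state[461:462] == "fn"))
  expect_true(all(p$state[463:1000] == "tn"))
  # row-major fill from the top-left
  expect_equal(p$row[1:26], c(rep(1L, 25), 2L))
  expect_equal(p$col[1:3], 1:3)
})

test_that("layout handles the degenerate single-person table", {
  lay <- nf_layout(nf_table(0, 0, 0, 1), grid_spec(rows = 1, cols = 1))
  expect_equal(nrow(lay$placements), 1)
  expect_equal(lay$placements$state, "tn")
  expect_equal(lay$placements$event, 0L)
})

test_that("layout fails loudly when the grid cannot hold the population", {
  expect_error(nf_layout(nf_table(1, 1, 1, 1), grid_spec(rows = 1, cols = 3)),
               "capacity")
})

test_that("scattered placement is reproducible and conserves states", {
  t <- nf_table(5, 20, 3, 72)
  a <- nf_layout(t, arrange = "scatter", seed = 7)
  b <- nf_layout(t, arrange = "scatter", seed = 7)
  expect_identical(a$placements, b$placements)
  expect_error(nf_layout(t, arrange = "scatter"), "seed")
  expect_equal(as.vector(table(a$placements$state)[c("tp", "fp", "fn", "tn")]),
               c(5, 20, 3, 72))
})

test_that("rendering is a pure function of layout and style", {
  lay <- nf_layout(nf_table(34, 426, 2, 538))
  expect_identical(render_svg(lay), render_svg(lay))
  expect_false(identical(render_svg(lay),
                         render_svg(lay, nf_style(palette = "colourblind"))))
})

test_that("the rendered diagram carries one icon per person, coded two ways", {
  style <- nf_style()
  svg <- render_svg(nf_layout(nf_table(34, 426, 2, 538)), style)
  expect_equal(count_pat(svg, 'class="icon'), 1000)
  expect_equal(count_pat(svg, paste0('fill="', style$at_risk_col, '"')),
               460 + 2)   # 460 cells + 2 legend swatches
  expect_equal(count_pat(svg, paste0('fill="', style$event_col, '"')),
               36 + 2)    # 36 shaded icons + 2 legend swatches

  q <- render_svg(nf_layout(nf_table(36, 110, 54, 800)), style)
  expect_equal(count_pat(q, 'class="icon'), 1000)
  expect_equal(count_pat(q, paste0('fill="', style$at_risk_col, '"')), 146 + 2)

  # legend lists all four states with their counts
  lay <- nf_layout(nf_table(36, 110, 54, 800))
  expect_equal(nrow(lay$legend), 4)
  expect_match(lay$legend$text[1], "at risk, event: 36")
})

test_that("diagram pairs share grid and styling and demand equal populations", {
  t <- nf_table(34, 426, 2, 538)
  pair_same <- render_diagram_pair(t, t)
  expect_identical(pair_same$before, pair_same$after)

  low <- t
  cut3 <- nf_table(24, 95, 12, 869)   # at-risk 460 vs 119
  pair <- render_diagram_pair(low, cut3)
  style <- nf_style()
  expect_equal(count_pat(pair$before,
                         paste0('fill="', style$at_risk_col, '"')), 460 + 2)
  expect_equal(count_pat(pair$after,
                         paste0('fill="', style$at_risk_col, '"')), 119 + 2)

  expect_error(render_diagram_pair(t, nf_rescale(t, 100)),
               "one reference population")
})

test_that("svg output is valid XML with stable float formatting", {
  svg <- render_svg(nf_layout(nf_table(2, 3, 1, 4),
                              grid_spec(rows = 2, cols = 5)))
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_false(grepl("\\d\\.\\d{3,}", svg))  # all floats at 2 decimals
})
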