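#' Grid specification for a population diagram
#'
#' @param rows,cols Positive integers; the grid must hold at least as many
#'   icons as the table's population. The default 25 columns by 40 rows
#'   holds the default reference population of 1000 in a compact aspect
#'   ratio.
#' @param icon `"circle"` or `"square"`.
#' @param cell_size Side of one grid cell in abstract (SVG user) units.
#' @param gap Space between cells, same units.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(rows = 40, cols = 25, icon = c("circle", "square"),
                      cell_size = 12, gap = 2) {
  rows <- stop_if_not_count(rows, "rows", positive = TRUE)
  cols <- stop_if_not_count(cols, "cols", positive = TRUE)
  icon <- match.arg(icon)
  stopifnot(is.numeric(cell_size), cell_size > 0, is.numeric(gap), gap >= 0)
  structure(list(rows = rows, cols = cols, icon = icon,
                 cell_size = cell_size, gap = gap),
            class = "grid_spec")
}

#' Diagram styling
#'
#' Colours follow the two-way coding of the population diagram: the cell
#' behind each icon is coloured by rule classification (red = at risk,
#' green = not at risk) and the icon itself is shaded when the person has
#' the event, unshaded when not. `palette = "colourblind"` switches to an
#' Okabe–Ito pairing (vermillion/sky blue).
#'
#' @param at_risk_col,not_at_risk_col Cell (background) fill colours.
#' @param event_col Icon fill for people who have the event.
#' @param non_event_col Icon fill for people who do not (default white, i.e.
#'   unshaded).
#' @param stroke Icon outline colour.
#' @param palette `"default"` or `"colourblind"`; explicit colour arguments
#'   override the palette.
#' @return An object of class `nf_style`.
#' @export
nf_style <- function(at_risk_col = NULL, not_at_risk_col = NULL,
                     event_col = NULL, non_event_col = NULL,
                     stroke = "#333333",
                     palette = c("default", "colourblind")) {
  palette <- match.arg(palette)
  base <- if (palette == "default") {
    list(at_risk_col = "#e07070", not_at_risk_col = "#8fce8f",
         event_col = "#1a1a1a", non_event_col = "#ffffff")
  } else {
    list(at_risk_col = "#d55e00", not_at_risk_col = "#56b4e9",
         event_col = "#000000", non_event_col = "#ffffff")
  }
  structure(list(
    at_risk_col = if (is.null(at_risk_col)) base$at_risk_col else at_risk_col,
    not_at_risk_col = if (is.null(not_at_risk_col)) base$not_at_risk_col else not_at_risk_col,
    event_col = if (is.null(event_col)) base$event_col else event_col,
    non_event_col = if (is.null(non_event_col)) base$non_event_col else non_event_col,
    stroke = stroke
  ), class = "nf_style")
}

state_order <- function(table) {
  # Group-contiguous block order: at-risk block first, events first within
  # each block, so the trade-off reads off the diagram as coloured regions.
  data.frame(
    state = c("tp", "fp", "fn", "tn"),
    n = c(table$tp, table$fp, table$fn, table$tn),
    event = c(1L, 0L, 1L, 0L),
    at_risk = c(1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Lay out a population diagram
#'
#' Assigns every person in the table one grid position and one of four icon
#' states (the 2x2 of event status by rule classification). Icons are
#' placed row-major from the top-left in group-contiguous blocks: at risk
#' with event (tp), at risk without event (fp), not at risk with event
#' (fn), not at risk without event (tn). `arrange = "scatter"` permutes
#' positions reproducibly from `seed` for the scattered icon-array style.
#'
#' @param table An [nf_table()].
#' @param grid A [grid_spec()]; capacity `rows * cols` must be at least the
#'   table's population.
#' @param arrange `"blocks"` (default) or `"scatter"`.
#' @param seed Integer seed, required when `arrange = "scatter"`.
#' @return An object of class `nf_layout`: placements (a data.frame of row,
#'   col, state, event, at_risk), the grid, a legend data.frame, and the
#'   source table.
#' @examples
#' lay <- nf_layout(nf_table(34, 426, 2, 538))
#' table(lay$placements$state)
#' @export
nf_layout <- function(table, grid = grid_spec(),
                      arrange = c("blocks", "scatter"), seed = NULL) {
  stopifnot(inherits(table, "nf_table"), inherits(grid, "grid_spec"))
  arrange <- match.arg(arrange)
  if (grid$rows * grid$cols < table$population) {
    stop(sprintf("grid capacity %d is smaller than population %d",
                 grid$rows * grid$cols, table$population), call. = FALSE)
  }
  st <- state_order(table)
  state <- rep(st$state, st$n)
  event <- rep(st$event, st$n)
  at_risk <- rep(st$at_risk, st$n)
  idx <- seq_len(table$population) - 1L
  if (arrange == "scatter") {
    if (is.null(seed)) {
      stop("`seed` is required for scattered placement", call. = FALSE)
    }
    idx <- local_seed(seed, sample(idx))
  }
  placements <- data.frame(
    row = idx %/% grid$cols + 1L,
    col = idx %% grid$cols + 1L,
    state = state, event = event, at_risk = at_risk,
    stringsAsFactors = FALSE
  )
  legend <- data.frame(
    state = st$state,
    text = sprintf("%s, %s: %d",
                   ifelse(st$at_risk == 1, "at risk", "not at risk"),
                   ifelse(st$event == 1, "event", "no event"),
                   st$n),
    stringsAsFactors = FALSE
  )
  structure(list(placements = placements, grid = grid, legend = legend,
                 table = table),
            class = "nf_layout")
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Render a population diagram as SVG
#'
#' One icon per person: a background cell rectangle coloured by rule
#' classification and a circle (or square) shaded by event status, grouped
#' in a `<g class="icon ...">` element per person, emitted in placement
#' order. The output is a pure function of layout and style — fixed float
#' formatting, a deterministic id scheme and no timestamps — so identical
#' inputs give byte-identical SVG, and diffs between renders are stable.
#'
#' @param layout An [nf_layout()].
#' @param style An [nf_style()].
#' @param caption Optional caption text placed below the grid.
#' @param file Optional path; when given the SVG is also written there.
#' @return The SVG document as a single string (invisibly when `file` is
#'   given).
#' @export
render_svg <- function(layout, style = nf_style(), caption = "", file = NULL) {
  stopifnot(inherits(layout, "nf_layout"), inherits(style, "nf_style"))
  g <- layout$grid
  step <- g$cell_size + g$gap
  legend_h <- 18 * (nrow(layout$legend) + 1)
  caption_h <- if (nzchar(caption)) 20 else 0
  width <- g$cols * step + g$gap
  height <- g$rows * step + g$gap + legend_h + caption_h

  icon_el <- function(i) {
    p <- layout$placements[i, ]
    x <- (p$col - 1) * step + g$gap
    y <- (p$row - 1) * step + g$gap
    cell_col <- if (p$at_risk == 1) style$at_risk_col else style$not_at_risk_col
    fill <- if (p$event == 1) style$event_col else style$non_event_col
    r <- g$cell_size / 2
    shape <- if (g$icon == "circle") {
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="0.5"/>',
              fmt2(x + r), fmt2(y + r), fmt2(r * 0.72), fill, style$stroke)
    } else {
      inset <- g$cell_size * 0.14
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="0.5"/>',
              fmt2(x + inset), fmt2(y + inset),
              fmt2(g$cell_size - 2 * inset), fmt2(g$cell_size - 2 * inset),
              fill, style$stroke)
    }
    sprintf('<g id="p%04d" class="icon %s"><rect class="cell" x="%s" y="%s" width="%s" height="%s" fill="%s"/>%s</g>',
            i, p$state, fmt2(x), fmt2(y), fmt2(g$cell_size), fmt2(g$cell_size),
            cell_col, shape)
  }

  icons <- vapply(seq_len(nrow(layout$placements)), icon_el, "")

  leg_y <- g$rows * step + g$gap + 14
  leg <- vapply(seq_len(nrow(layout$legend)), function(i) {
    st <- layout$legend$state[i]
    cell_col <- if (st %in% c("tp", "fp")) style$at_risk_col else style$not_at_risk_col
    fill <- if (st %in% c("tp", "fn")) style$event_col else style$non_event_col
    y <- leg_y + (i - 1) * 18
    paste0(
      sprintf('<rect x="4.00" y="%s" width="12.00" height="12.00" fill="%s"/>',
              fmt2(y), cell_col),
      sprintf('<circle cx="10.00" cy="%s" r="4.30" fill="%s" stroke="%s" stroke-width="0.5"/>',
              fmt2(y + 6), fill, style$stroke),
      sprintf('<text x="20.00" y="%s" font-size="11" font-family="sans-serif">%s</text>',
              fmt2(y + 10), layout$legend$text[i])
    )
  }, "")

  cap <- if (nzchar(caption)) {
    sprintf('<text class="caption" x="4.00" y="%s" font-size="12" font-family="sans-serif">%s</text>',
            fmt2(height - 6), caption)
  } else {
    '<!-- caption slot -->'
  }

  svg <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            fmt2(width), fmt2(height), fmt2(width), fmt2(height)),
    paste(icons, collapse = "\n"), "\n",
    paste(leg, collapse = "\n"), "\n",
    cap, "\n</svg>\n")
  if (!is.null(file)) {
    writeLines(svg, file, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Render two comparable population diagrams
#'
#' Renders a before/after pair (e.g. the same rule at two cut-points) with
#' identical grid, styling and legend geometry so the diagrams can be read
#' side by side; the populations must match.
#'
#' @param before,after [nf_table()] objects with equal population.
#' @param grid Shared [grid_spec()].
#' @param style Shared [nf_style()].
#' @param captions Character vector of two captions.
#' @return A list of two SVG strings, names `before` and `after`.
#' @export
render_diagram_pair <- function(before, after, grid = grid_spec(),
                                style = nf_style(),
                                captions = c("", "")) {
  stopifnot(inherits(before, "nf_table"), inherits(after, "nf_table"))
  if (before$population != after$population) {
    stop("both tables must share one reference population", call. = FALSE)
  }
  list(
    before = render_svg(nf_layout(before, grid), style, captions[1]),
    after = render_svg(nf_layout(after, grid), style, captions[2])
  )
}

#' Plot a population diagram on the active graphics device
#'
#' Base-graphics rendering of the same layout used by [render_svg()], for
#' interactive inspection.
#'
#' @param x An [nf_table()].
#' @param grid A [grid_spec()].
#' @param style An [nf_style()].
#' @param ... Unused.
#' @export
plot.nf_table <- function(x, grid = grid_spec(), style = nf_style(), ...) {
  lay <- nf_layout(x, grid)
  p <- lay$placements
  step <- grid$cell_size + grid$gap
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, grid$cols * step),
                        ylim = c(grid$rows * step, 0), asp = 1)
  xx <- (p$col - 1) * step
  yy <- (p$row - 1) * step
  graphics::rect(xx, yy, xx + grid$cell_size, yy + grid$cell_size,
                 col = ifelse(p$at_risk == 1, style$at_risk_col,
                              style$not_at_risk_col), border = NA)
  graphics::points(xx + grid$cell_size / 2, yy + grid$cell_size / 2,
                   pch = 21, cex = 0.6,
                   bg = ifelse(p$event == 1, style$event_col,
                               style$non_event_col))
  invisible(lay)
}
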