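# Nested CDR3 treemaps: the canvas is divided first into V rectangles,
# each V rectangle into V-J rectangles, and each of those into
# V-J-CDR3(nt) leaves, with areas proportional to read frequency.
# Within every level rectangles are squarified in descending area and the
# whole layout is mirrored so the largest sits at the bottom right and
# the smallest at the top left.

# Squarified packing of weights (descending order expected) into the
# rectangle (x, y, w, h); origin top-left, fills from the top-left.
# Returns a data.frame of sub-rectangles in input order. Areas are exact:
# each row of the packing receives width (or height) proportional to its
# weight sum, and splits it proportionally.
squarify <- function(weights, x, y, w, h) {
  n <- length(weights)
  out <- data.frame(x = numeric(n), y = numeric(n), w = numeric(n), h = numeric(n))
  scale <- (w * h) / sum(weights)
  areas <- weights * scale
  i <- 1L
  while (i <= n) {
    short <- min(w, h)
    # grow the row while the worst aspect ratio improves
    j <- i
    row <- areas[i]
    worst_of <- function(row_sum, amin, amax, short) {
      s2 <- row_sum^2
      max(short^2 * amax / s2, s2 / (short^2 * amin))
    }
    best <- worst_of(row, areas[i], areas[i], short)
    while (j < n) {
      cand <- row + areas[j + 1L]
      wr <- worst_of(cand, min(areas[i:(j + 1L)]), max(areas[i:(j + 1L)]), short)
      if (wr > best) break
      j <- j + 1L; row <- cand; best <- wr
    }
    thick <- row / short
    off <- 0
    for (k in i:j) {
      len <- areas[k] / thick
      if (w <= h) {      # row laid horizontally across the top
        out$x[k] <- x + off; out$y[k] <- y; out$w[k] <- len; out$h[k] <- thick
      } else {           # column laid vertically along the left
        out$x[k] <- x; out$y[k] <- y + off; out$w[k] <- thick; out$h[k] <- len
      }
      off <- off + len
    }
    if (w <= h) { y <- y + thick; h <- h - thick } else { x <- x + thick; w <- w - thick }
    i <- j + 1L
  }
  out
}

#' Lay out a three-level nested CDR3 treemap
#'
#' Levels: V gene, V-J combination, V-J-CDR3 nucleotide sequence. Leaf
#' area / canvas area equals the clonotype's read frequency; children
#' tile their parent exactly. Rectangles at every level are ordered by
#' area, largest at the bottom right. Colors are drawn from a seeded
#' generator so plots are reproducible but palettes differ between seeds.
#'
#' @param table A `clonotype_table`.
#' @param canvas `c(width, height)` (default 1000 x 600).
#' @param seed Integer seed for colors.
#' @return Object of class `treemap_layout`: list with `canvas` and
#'   `rectangles` (level, label, v, j, cdr3, x, y, w, h, color).
#' @export
layout_treemap <- function(table, canvas = c(1000, 600), seed = 1) {
  if (nrow(table) == 0L) stop("empty clonotype table")
  if (any(canvas <= 0)) stop("zero-area canvas")
  W <- canvas[1]; H <- canvas[2]
  agg <- stats::aggregate(copies ~ v_call + j_call + cdr3_nt, data = as.data.frame(table), sum)

  mirror <- function(df, X, Y, WW, HH) {
    df$x <- X + (WW - (df$x - X) - df$w)
    df$y <- Y + (HH - (df$y - Y) - df$h)
    df
  }
  order_desc <- function(d, key) d[order(-d$weight, d[[key]]), , drop = FALSE]

  rects <- list()
  v_tab <- stats::aggregate(copies ~ v_call, agg, sum)
  names(v_tab)[2] <- "weight"
  v_tab <- order_desc(v_tab, "v_call")
  v_rects <- squarify(v_tab$weight, 0, 0, W, H)
  for (vi in seq_len(nrow(v_tab))) {
    vr <- v_rects[vi, ]
    rects[[length(rects) + 1L]] <- data.frame(
      level = "V", label = v_tab$v_call[vi], v = v_tab$v_call[vi],
      j = NA_character_, cdr3 = NA_character_,
      x = vr$x, y = vr$y, w = vr$w, h = vr$h, stringsAsFactors = FALSE)
    sub <- agg[agg$v_call == v_tab$v_call[vi], , drop = FALSE]
    vj_tab <- stats::aggregate(copies ~ j_call, sub, sum)
    names(vj_tab)[2] <- "weight"
    vj_tab <- order_desc(vj_tab, "j_call")
    vj_rects <- squarify(vj_tab$weight, vr$x, vr$y, vr$w, vr$h)
    for (ji in seq_len(nrow(vj_tab))) {
      jr <- vj_rects[ji, ]
      rects[[length(rects) + 1L]] <- data.frame(
        level = "VJ", label = paste(v_tab$v_call[vi], vj_tab$j_call[ji]),
        v = v_tab$v_call[vi], j = vj_tab$j_call[ji], cdr3 = NA_character_,
        x = jr$x, y = jr$y, w = jr$w, h = jr$h, stringsAsFactors = FALSE)
      leaves <- sub[sub$j_call == vj_tab$j_call[ji], , drop = FALSE]
      leaves$weight <- leaves$copies
      leaves <- order_desc(leaves, "cdr3_nt")
      lf <- squarify(leaves$weight, jr$x, jr$y, jr$w, jr$h)
      for (li in seq_len(nrow(leaves))) {
        rects[[length(rects) + 1L]] <- data.frame(
          level = "VJCDR3",
          label = paste(v_tab$v_call[vi], vj_tab$j_call[ji], leaves$cdr3_nt[li]),
          v = v_tab$v_call[vi], j = vj_tab$j_call[ji], cdr3 = leaves$cdr3_nt[li],
          x = lf$x[li], y = lf$y[li], w = lf$w[li], h = lf$h[li],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rects)
  df <- mirror(df, 0, 0, W, H)
  ncol_leaf <- sum(df$level == "VJCDR3")
  cols <- with_seed(seed, grDevices::hsv(runif(nrow(df)), 0.45 + 0.4 * runif(nrow(df)),
                                         0.75 + 0.2 * runif(nrow(df))))
  df$color <- cols
  structure(list(canvas = c(width = W, height = H), rectangles = df),
            class = "treemap_layout")
}

#' Render a treemap layout as SVG
#'
#' One rounded rectangle per leaf (plus level-1/2 outlines), labels in
#' element metadata. Deterministic for a fixed layout.
#'
#' @param layout A `treemap_layout`.
#' @param corner_radius Corner rounding in px (default 3).
#' @param path Optional file to write.
#' @return SVG document as a character scalar (invisibly when `path` is
#'   given).
#' @export
render_svg <- function(layout, corner_radius = 3, path = NULL) {
  cv <- layout$canvas
  df <- layout$rectangles
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  header <- sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
                    cv["width"], cv["height"], cv["width"], cv["height"])
  leaf <- df[df$level == "VJCDR3", , drop = FALSE]
  body_leaf <- sprintf('  <rect class="leaf" data-label="%s" x="%.4f" y="%.4f" width="%.4f" height="%.4f" rx="%g" fill="%s" stroke="white" stroke-width="0.5"/>',
                       esc(leaf$label), leaf$x, leaf$y, leaf$w, leaf$h,
                       corner_radius, leaf$color)
  lvl <- df[df$level != "VJCDR3", , drop = FALSE]
  body_lvl <- sprintf('  <rect class="outline-%s" data-label="%s" x="%.4f" y="%.4f" width="%.4f" height="%.4f" rx="%g" fill="none" stroke="black" stroke-width="%s"/>',
                      tolower(lvl$level), esc(lvl$label), lvl$x, lvl$y,
                      lvl$w, lvl$h, corner_radius,
                      ifelse(lvl$level == "V", "2", "1"))
  svg <- paste(c(header, body_leaf, body_lvl, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}
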