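# Fixed 5x5 bitmap capitals. A hand-drawn font table keeps text rendering
# bit-stable across platforms (no font library, no anti-aliasing): glyph
# pixels are exactly 1.0, background exactly 0.0.

glyph_rows <- list(
  A = c(".###.", "#...#", "#####", "#...#", "#...#"),
  B = c("####.", "#...#", "####.", "#...#", "####."),
  C = c(".####", "#....", "#....", "#....", ".####"),
  D = c("####.", "#...#", "#...#", "#...#", "####."),
  E = c("#####", "#....", "####.", "#....", "#####"),
  F = c("#####", "#....", "####.", "#....", "#...."),
  G = c(".####", "#....", "#..##", "#...#", ".####"),
  H = c("#...#", "#...#", "#####", "#...#", "#...#"),
  I = c("#####", "..#..", "..#..", "..#..", "#####"),
  J = c("..###", "...#.", "...#.", "#..#.", ".##.."),
  K = c("#...#", "#..#.", "###..", "#..#.", "#...#"),
  L = c("#....", "#....", "#....", "#....", "#####"),
  M = c("#...#", "##.##", "#.#.#", "#...#", "#...#"),
  N = c("#...#", "##..#", "#.#.#", "#..##", "#...#"),
  O = c(".###.", "#...#", "#...#", "#...#", ".###."),
  P = c("####.", "#...#", "####.", "#....", "#...."),
  Q = c(".###.", "#...#", "#.#.#", "#..#.", ".##.#"),
  R = c("####.", "#...#", "####.", "#..#.", "#...#"),
  S = c(".####", "#....", ".###.", "....#", "####."),
  T = c("#####", "..#..", "..#..", "..#..", "..#.."),
  U = c("#...#", "#...#", "#...#", "#...#", ".###."),
  V = c("#...#", "#...#", "#...#", ".#.#.", "..#.."),
  W = c("#...#", "#...#", "#.#.#", "##.##", "#...#"),
  X = c("#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
  Y = c("#...#", ".#.#.", "..#..", "..#..", "..#.."),
  Z = c("#####", "...#.", "..#..", ".#...", "#####"),
  ` ` = c(".....", ".....", ".....", ".....", ".....")
)

glyph_matrix <- function(ch) {
  rows <- glyph_rows[[ch]]
  m <- matrix(0, 5, 5)
  for (r in 1:5) m[r, ] <- as.integer(strsplit(rows[r], "")[[1]] == "#")
  m
}

#' Render text as a square intensity patch with a glyph mask
#'
#' Renders `text` in a fixed 5x5-per-glyph bitmap font (capitals A-Z and
#' space), glyphs separated by a one-pixel gap, and embeds the rendering
#' centred in an `m` x `m` patch. Foreground pixels are 1.0, background 0.0;
#' the logical `mask` marks exactly the glyph pixels. Rendering is
#' deterministic and bit-stable: no font library is involved.
#'
#' @param text Non-empty string of supported characters.
#' @param m Patch side length; must fit the rendering
#'   (width `5 * nchar + (nchar - 1)`, height 5).
#' @return A list with `patch` (m x m numeric matrix in \[0,1\]) and `mask`
#'   (m x m logical matrix of glyph pixels).
#' @examples
#' a <- render_text_patch("A", 5)
#' sum(a$mask)
#' @export
render_text_patch <- function(text, m) {
  if (!is.character(text) || length(text) != 1 || nchar(text) == 0) {
    abort("`text` must be a non-empty string.", class = "ufm_invalid_argument")
  }
  chars <- strsplit(text, "")[[1]]
  bad <- unique(chars[!chars %in% names(glyph_rows)])
  if (length(bad) > 0) {
    abort(
      paste0("unsupported glyph(s): ", paste(sQuote(bad), collapse = ", "),
             "; the bitmap font covers A-Z and space."),
      class = "ufm_unsupported_glyph"
    )
  }
  k <- length(chars)
  width <- 5L * k + (k - 1L)
  if (m < 5L || m < width) {
    abort(sprintf("patch side m = %d cannot fit %d glyph(s) (need >= %d).",
                  m, k, max(5L, width)),
          class = "ufm_invalid_argument")
  }
  strip <- matrix(0, 5, width)
  for (i in seq_len(k)) {
    strip[, (i - 1L) * 6L + 1:5] <- glyph_matrix(chars[i])
  }
  patch <- matrix(0, m, m)
  r0 <- (m - 5L) %/% 2L
  c0 <- (m - width) %/% 2L
  patch[r0 + 1:5, c0 + seq_len(width)] <- strip
  list(patch = patch, mask = patch > 0)
}
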