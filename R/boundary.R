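## boundary: Freeman chain-code tracing of the lesion border.
##
## Direction symbols increase counter-clockwise:
##   0=E, 1=NE, 2=N, 3=NW, 4=W, 5=SW, 6=S, 7=SE
## in image coordinates (row grows downward). The trace itself walks the
## border clockwise (Moore-neighbor tracing with Jacob's stopping criterion).

# (drow, dcol) per symbol 0..7
DIR_VECTORS <- matrix(c(0, 1,  -1, 1,  -1, 0,  -1, -1,
                        0, -1,  1, -1,  1, 0,   1, 1),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(0:7, c("dr", "dc")))

# clockwise neighbor ring used by the tracer: E, SE, S, SW, W, NW, N, NE
MOORE_CW <- matrix(c(0, 1,  1, 1,  1, 0,  1, -1,
                     0, -1, -1, -1, -1, 0, -1, 1),
                   ncol = 2, byrow = TRUE)

#' Chain-code container
#' @param start `(row, col)` of the starting boundary pixel.
#' @param moves integer vector of direction symbols in 0..7.
#' @return object of class `chain_code`.
#' @export
chain_code <- function(start, moves) {
  structure(list(start = as.integer(start), moves = as.integer(moves)),
            class = "chain_code")
}

#' @export
print.chain_code <- function(x, ...) {
  cat(sprintf("<chain_code start=(%d,%d) length=%d>\n",
              x$start[1], x$start[2], length(x$moves)))
  invisible(x)
}

#' Serialize / parse a chain code as text (`start_row start_col : d1 d2 ...`)
#' @param x a `chain_code`.
#' @return single character string.
#' @export
format_chain_code <- function(x) {
  paste(x$start[1], x$start[2], ":", paste(x$moves, collapse = " "))
}

#' @rdname format_chain_code
#' @param s string produced by [format_chain_code()].
#' @export
parse_chain_code <- function(s) {
  parts <- strsplit(trimws(s), ":", fixed = TRUE)[[1]]
  st <- scan(text = parts[1], quiet = TRUE)
  mv <- if (length(parts) > 1L && nzchar(trimws(parts[2])))
    scan(text = parts[2], quiet = TRUE) else integer(0)
  chain_code(st, mv)
}

#' Starting pixel for the boundary trace
#'
#' The foreground pixel with minimal row, ties broken by minimal column
#' (the topmost-then-leftmost "upmost pixel" where every border cycle starts
#' and ends).
#'
#' @param m standardized lesion mask.
#' @return integer `(row, col)`.
#' @export
find_start_pixel <- function(m) {
  m <- as_mask(m)
  idx <- which(unclass(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) abort2("empty mask", "abruptcut_data_error")
  top <- min(idx[, 1])
  c(top, min(idx[idx[, 1] == top, 2]))
}

is_fg <- function(bits, r, c) {
  r >= 1 && r <= nrow(bits) && c >= 1 && c <= ncol(bits) && bits[r, c]
}

#' Trace the lesion boundary as a Freeman chain code
#'
#' Moore-neighbor tracing, clockwise in image coordinates, starting at the
#' topmost-leftmost foreground pixel and stopping by Jacob's criterion (the
#' start pixel is re-entered from the same backtrack). Pixels outside the
#' image count as background. A single isolated pixel yields an empty move
#' list.
#'
#' @param m standardized lesion mask (single 8-connected component).
#' @param start optional `(row, col)` start; defaults to
#'   [find_start_pixel()]. Must be a boundary pixel.
#' @return a [chain_code()].
#' @export
trace_chain_code <- function(m, start = NULL) {
  m <- as_mask(m)
  bits <- unclass(m)
  if (is.null(start)) start <- find_start_pixel(m)
  start <- as.integer(start)
  if (!is_fg(bits, start[1], start[2]))
    abort2("start pixel is not foreground", "abruptcut_data_error")
  nb_bg <- FALSE
  for (k in 1:8)
    if (!is_fg(bits, start[1] + MOORE_CW[k, 1], start[2] + MOORE_CW[k, 2]))
      nb_bg <- TRUE
  if (!nb_bg)
    abort2("start pixel is interior, not on the boundary",
           "abruptcut_data_error")

  sym_of <- function(dr, dc) {
    for (s in 0:7)
      if (DIR_VECTORS[s + 1, 1] == dr && DIR_VECTORS[s + 1, 2] == dc)
        return(s)
    stop("non-adjacent step")  # cannot happen
  }

  back0 <- c(start[1] - 1L, start[2])  # above the topmost pixel: background
  cur <- start; back <- back0
  moves <- integer(0)
  first_next <- NULL
  limit <- 4L * sum(bits) + 8L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > limit)
      abort2("boundary trace failed to close", "abruptcut_data_error")
    # exact state repeat: back at the start with the initial backtrack
    if (iter > 1L && cur[1] == start[1] && cur[2] == start[2] &&
        back[1] == back0[1] && back[2] == back0[2])
      return(chain_code(start, moves))
    # position of backtrack in cur's clockwise ring
    db <- back - cur
    kb <- which(MOORE_CW[, 1] == db[1] & MOORE_CW[, 2] == db[2])
    nxt <- NULL
    for (j in 1:8) {
      k <- ((kb + j - 1L) %% 8L) + 1L  # first neighbor after the backtrack
      cand <- c(cur[1] + MOORE_CW[k, 1], cur[2] + MOORE_CW[k, 2])
      if (is_fg(bits, cand[1], cand[2])) {
        nxt <- cand
        kprev <- ((k - 2L) %% 8L) + 1L
        newback <- c(cur[1] + MOORE_CW[kprev, 1], cur[2] + MOORE_CW[kprev, 2])
        break
      }
    }
    if (is.null(nxt)) {             # isolated pixel
      return(chain_code(start, integer(0)))
    }
    # stopping criterion: about to leave the start pixel along the same
    # move as on the very first iteration -> the cycle would repeat
    if (iter > 1L && cur[1] == start[1] && cur[2] == start[2] &&
        nxt[1] == first_next[1] && nxt[2] == first_next[2])
      return(chain_code(start, moves))
    moves <- c(moves, sym_of(nxt[1] - cur[1], nxt[2] - cur[2]))
    if (is.null(first_next)) first_next <- nxt
    cur <- nxt; back <- newback
  }
}

#' Reconstruct the ordered boundary path from a chain code
#'
#' @param cc a [chain_code()].
#' @return a `boundary_path`: integer matrix with columns `row`, `col`, one
#'   row per boundary pixel, cyclic (the final move returns to the start and
#'   is not duplicated).
#' @export
chain_to_path <- function(cc) {
  stopifnot(inherits(cc, "chain_code"))
  n <- length(cc$moves)
  if (n == 0L) {
    p <- matrix(cc$start, 1, 2, dimnames = list(NULL, c("row", "col")))
    return(structure(p, class = c("boundary_path", "matrix", "array")))
  }
  steps <- DIR_VECTORS[cc$moves + 1L, , drop = FALSE]
  rows <- cc$start[1] + cumsum(steps[, 1])
  cols <- cc$start[2] + cumsum(steps[, 2])
  if (rows[n] != cc$start[1] || cols[n] != cc$start[2])
    abort2("chain code does not close", "abruptcut_data_error")
  p <- cbind(row = c(cc$start[1], rows[-n]), col = c(cc$start[2], cols[-n]))
  structure(p, class = c("boundary_path", "matrix", "array"))
}

#' Trace a mask and return its boundary path directly
#' @inheritParams trace_chain_code
#' @return a `boundary_path` matrix.
#' @export
trace_boundary <- function(m, start = NULL) {
  chain_to_path(trace_chain_code(m, start))
}

#' Center of mass of the lesion foreground
#' @param m lesion mask.
#' @return named numeric `c(x = mean col, y = mean row)` (sub-pixel).
#' @export
mask_centroid <- function(m) {
  m <- as_mask(m)
  idx <- which(unclass(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) abort2("empty mask", "abruptcut_data_error")
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' Step along a cyclic path
#' @param path a `boundary_path` (or anything with rows).
#' @param i current 1-based index.
#' @param k number of steps forward (>= 1).
#' @return the 1-based index `k` steps further, wrapping around.
#' @export
step_along <- function(path, i, k) {
  n <- if (is.matrix(path)) nrow(path) else length(path)
  ((i - 1L + k) %% n) + 1L
}
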