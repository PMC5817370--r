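# Internal helpers shared across modules: condition constructors, seeded RNG
# scoping, matrix shifts with replicated borders, 8-connected labelling,
# boundary extraction and signed distance transforms.

#' @importFrom stats rnorm sd dnorm
#' @importFrom utils head tail write.csv read.csv
NULL

stop_petct <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "petctseg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

is_raster <- function(x) is.matrix(x) && is.numeric(x)

check_raster <- function(x, name = "raster") {
  if (!is_raster(x)) {
    stop_petct(sprintf("`%s` must be a numeric matrix", name), "parameter_error")
  }
  invisible(x)
}

check_same_grid <- function(a, b, names = c("a", "b")) {
  if (!identical(dim(a), dim(b))) {
    stop_petct(sprintf("`%s` and `%s` must share the same grid", names[1], names[2]),
               "parameter_error")
  }
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by (dr, dc), replicating edge rows/columns.
shift_mat <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 8- (default) or 4-connected component labels; 0 marks background.
# Labels are assigned in row-major order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)
  offs <- if (connectivity == 8L) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  } else {
    list(c(1L, 0L), c(0L, 1L))
  }
  r <- (fg - 1L) %% nr + 1L
  c_ <- (fg - 1L) %/% nr + 1L
  inmask <- matrix(FALSE, nr, nc); inmask[fg] <- TRUE
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c_ + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- inmask[lin2]
    if (!any(hit)) next
    from <- c(from, fg[ok][hit])
    to <- c(to, lin2[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(match(from, fg), match(to, fg)))
  }
  comp <- igraph::components(g)$membership
  rm_order <- order((r - 1L) * nc + c_)  # row-major rank of each fg pixel
  first_seen <- !duplicated(comp[rm_order])
  relabel <- integer(max(comp))
  relabel[comp[rm_order][first_seen]] <- seq_len(sum(first_seen))
  out[fg] <- relabel[comp]
  out
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)))
  matrix(as.integer(f > 0), nrow(mask), ncol(mask))
}

# Foreground pixels with at least one background 4-neighbour; pixels on the
# image border count the outside as background.
mask_boundary_pixels <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb_bg <- (!pad[1:nr, 2:(nc + 1L)]) | (!pad[3:(nr + 2L), 2:(nc + 1L)]) |
    (!pad[2:(nr + 1L), 1:nc]) | (!pad[2:(nr + 1L), 3:(nc + 2L)])
  which(core & nb_bg, arr.ind = TRUE)
}

# Signed Euclidean distance to the mask boundary, positive inside.
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (all(m > 0) || all(m == 0)) {
    stop_petct("mask must contain both foreground and background",
               "degenerate_input_error")
  }
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1 - m))
  din - dout
}

# Integer (dr, dc) offsets of pixels whose centre lies within `r` pixels.
disk_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dr = s, dc = s)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  list(dr = as.integer(g$dr), dc = as.integer(g$dc))
}

# Largest closed polyline of the 0.5-level of a binary mask, as (row, col).
trace_mask_contour <- function(mask) {
  cl <- grDevices::contourLines(x = seq_len(nrow(mask)), y = seq_len(ncol(mask)),
                                z = mask, levels = 0.5)
  if (length(cl) == 0L) {
    stop_petct("mask has no 0.5-level contour", "empty_mask_error")
  }
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(lens)]]
  v <- cbind(row = p$x, col = p$y)
  closed <- isTRUE(all.equal(v[1, ], v[nrow(v), ], check.attributes = FALSE))
  if (!closed) {
    v <- rbind(v, v[1, ])
    closed <- TRUE
  }
  list(vertices = v, closed = closed)
}
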