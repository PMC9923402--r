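#' Label 8-connected foreground components
#'
#' Connected-component labelling with 8-connectivity (edge or corner
#' adjacency). Labels are consecutive integers `1..n`, assigned in raster
#' order of each component's first pixel (column-major, matching R's linear
#' indexing).
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(array(0L, dim(mask)))
  # bwlabel is 4-connected; merge labels that touch diagonally with union-find
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    h <- nrow(lab); w <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
      cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # up-right
    )
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(n), find, integer(1L))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  compact_labels(lab)
}

# Renumber positive labels to consecutive 1..n, ordered by each label's first
# pixel in column-major raster order. Background (0) untouched.
compact_labels <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(array(0L, dim(lab)))
  old <- lab[fg]
  first <- vapply(split(fg, old), min, numeric(1L))
  order_ids <- as.integer(names(first))[order(first)]
  map <- integer(max(old))
  map[order_ids] <- seq_along(order_ids)
  out <- array(0L, dim(lab))
  out[fg] <- map[old]
  out
}

component_sizes <- function(lab) {
  if (max(lab) == 0L) return(integer(0L))
  tabulate(lab[lab > 0L], nbins = max(lab))
}
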