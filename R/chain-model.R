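## Rodrigues rotation matrix about unit axis u by theta (radians).
.rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Rotation taking unit vector a onto unit vector b.
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    ## pick any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2],
            a[3] * p[1] - a[1] * p[3],
            a[1] * p[2] - a[2] * p[1])
    return(.rotation_matrix(ax, pi))
  }
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  .rotation_matrix(ax, acos(max(-1, min(1, d))))
}

.new_pivots <- function(n) {
  if (n < 2L)
    return(data.frame(from = integer(0), frozen = logical(0),
                      win_count = integer(0)))
  data.frame(from = seq_len(n - 1L), frozen = FALSE, win_count = 0L)
}

#' Build an extended coarse chain from an annotated sequence
#'
#' One C-alpha-level site per residue on a straight line at the virtual bond
#' spacing, carrying the residue's charge and hydropathy tags. All pivots
#' start unfrozen with zero win count.
#'
#' @param seq An [annotate_sequence()] result.
#' @param bond_length Virtual C-alpha to C-alpha bond length (nm).
#' @return Object of class \code{coarse_chain}: positions \code{xyz} (nm),
#'   tags \code{q}, \code{h}, residue \code{span} per site, \code{rigid_group}
#'   ids, per-site orientation \code{frame}s and residue offsets \code{local}
#'   (for re-expansion), and the \code{pivots} table.
#' @export
build_extended_chain <- function(seq, bond_length = 0.38) {
  stopifnot(inherits(seq, "annotated_seq"), bond_length > 0)
  n <- length(seq$residues)
  chain <- list(
    xyz = cbind(x = (seq_len(n) - 1) * bond_length, y = 0, z = 0),
    q = seq$q, h = seq$h,
    span = cbind(first = seq_len(n), last = seq_len(n)),
    rigid_group = rep(NA_integer_, n),
    frame = rep(list(diag(3)), n),
    local = rep(list(matrix(0, 1, 3)), n),
    pivots = .new_pivots(n),
    residues = seq$residues, n_res = n, bond_length = bond_length)
  class(chain) <- "coarse_chain"
  chain
}

#' Ideal secondary-structure template parameters
#'
#' Standard C-alpha geometry: alpha helix with 0.15 nm rise and 100 degrees
#' turn per residue on a 0.23 nm radius; extended strand at 0.35 nm rise per
#' residue.
#'
#' @return Named list with \code{helix} and \code{strand} parameter sets
#'   (fields \code{rise}, \code{turn_deg}, \code{radius}).
#' @export
ss_templates <- function() {
  list(helix  = list(rise = 0.15, turn_deg = 100, radius = 0.23),
       strand = list(rise = 0.35, turn_deg = 0, radius = 0))
}

## Ideal template coordinates for m residues, first residue at the origin.
.template_coords <- function(tpl, m) {
  k <- seq_len(m) - 1
  phi <- k * tpl$turn_deg * pi / 180
  xyz <- cbind(tpl$radius * cos(phi), tpl$radius * sin(phi), k * tpl$rise)
  sweep(xyz, 2, xyz[1, ])
}

#' Insert rigid secondary-structure templates
#'
#' Replaces the sites of every predicted helix/sheet region by ideal template
#' geometry, rigidly oriented along the region's original start-to-end
#' direction and anchored at its first site. Region sites share a rigid-group
#' id and every pivot interior to a region is permanently frozen, making the
#' inserted geometry immutable for the rest of the run.
#'
#' @param chain A residue-level chain from [build_extended_chain()].
#' @param ss An \code{ss_annotation} from [predict_secondary()] (labels must
#'   align with the chain's residues).
#' @param templates Template parameters, see [ss_templates()].
#' @return The modified chain.
#' @export
insert_templates <- function(chain, ss, templates = ss_templates()) {
  stopifnot(inherits(chain, "coarse_chain"), inherits(ss, "ss_annotation"))
  n <- nrow(chain$xyz)
  if (length(ss$labels) != n || chain$n_res != n)
    stop("ss labels must align with a residue-level chain")
  reg <- ss$regions
  if (nrow(reg) == 0L) return(chain)
  o <- order(reg$start)
  reg <- reg[o, ]
  if (any(reg$start[-1] <= reg$end[-nrow(reg)]))
    stop("overlapping secondary-structure regions")
  for (g in seq_len(nrow(reg))) {
    i <- reg$start[g]; j <- reg$end[g]; m <- j - i + 1L
    tpl <- if (reg$kind[g] == "H") templates$helix else templates$strand
    if (m > 1L) {
      d <- chain$xyz[j, ] - chain$xyz[i, ]
      R <- if (sqrt(sum(d^2)) < 1e-12) diag(3) else .rotation_between(c(0, 0, 1), d)
      tc <- .template_coords(tpl, m) %*% t(R)
      chain$xyz[i:j, ] <- sweep(tc, 2, chain$xyz[i, ], "+")
      chain$pivots$frozen[chain$pivots$from %in% i:(j - 1L)] <- TRUE
    }
    chain$rigid_group[i:j] <- g
  }
  chain
}

#' Collapse rigid regions to single effective sites
#'
#' Each rigid secondary-structure region becomes one site at the region
#' centroid, tagged with the region's summed charge and summed hydropathy;
#' member geometry is retained in the site's local frame so that
#' [expand_to_residues()] can reconstruct per-residue coordinates after
#' folding. Unstructured sites are unchanged. Totals of charge and hydropathy
#' are conserved.
#'
#' @param chain A chain after [insert_templates()].
#' @return The coarse-grained chain (all pivots reset, unfrozen).
#' @export
coarse_grain_regions <- function(chain) {
  stopifnot(inherits(chain, "coarse_chain"))
  if (all(is.na(chain$rigid_group))) return(chain)
  n <- nrow(chain$xyz)
  xyz <- NULL; q <- h <- numeric(0)
  span <- NULL; rg <- integer(0)
  frame <- list(); local <- list()
  i <- 1L
  while (i <= n) {
    g <- chain$rigid_group[i]
    if (is.na(g)) {
      xyz <- rbind(xyz, chain$xyz[i, ])
      q <- c(q, chain$q[i]); h <- c(h, chain$h[i])
      span <- rbind(span, chain$span[i, ])
      rg <- c(rg, NA_integer_)
      frame[[length(frame) + 1L]] <- chain$frame[[i]]
      local[[length(local) + 1L]] <- chain$local[[i]]
      i <- i + 1L
    } else {
      mem <- which(chain$rigid_group == g)
      cen <- colMeans(chain$xyz[mem, , drop = FALSE])
      xyz <- rbind(xyz, cen)
      q <- c(q, sum(chain$q[mem])); h <- c(h, sum(chain$h[mem]))
      span <- rbind(span, c(min(chain$span[mem, 1]), max(chain$span[mem, 2])))
      rg <- c(rg, g)
      frame[[length(frame) + 1L]] <- diag(3)
      local[[length(local) + 1L]] <- sweep(chain$xyz[mem, , drop = FALSE], 2, cen)
      i <- max(mem) + 1L
    }
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  colnames(span) <- c("first", "last")
  out <- list(xyz = xyz, q = q, h = h, span = span, rigid_group = rg,
              frame = frame, local = local,
              pivots = .new_pivots(nrow(xyz)),
              residues = chain$residues, n_res = chain$n_res,
              bond_length = chain$bond_length)
  class(out) <- "coarse_chain"
  out
}

## Which sites move for a pivot: the smaller non-empty flank
## (ties -> C-terminal flank).
.mobile_block <- function(n, k) {
  nN <- k - 1L
  nC <- n - k - 1L
  if (nN == 0L && nC == 0L) return(integer(0))
  if (nC == 0L || (nN > 0L && nN < nC)) seq_len(nN) else (k + 2L):n
}

#' Rotate one chain block about a pivot bond
#'
#' Rigid Rodrigues rotation of the smaller flank (ties: the C-terminal flank)
#' about the axis through the pivot-bond sites. All within-block pairwise
#' distances are preserved; per-site orientation frames rotate with the block
#' so coarse-grained regions re-expand correctly.
#'
#' @param chain A \code{coarse_chain}.
#' @param pivot Pivot index k (the bond between sites k and k+1); must not be
#'   frozen.
#' @param theta Rotation angle (radians).
#' @return The rotated chain.
#' @export
rotate_about_pivot <- function(chain, pivot, theta) {
  stopifnot(inherits(chain, "coarse_chain"))
  n <- nrow(chain$xyz)
  if (pivot < 1L || pivot > n - 1L) stop("pivot index out of range")
  if (chain$pivots$frozen[pivot]) stop("cannot rotate a frozen pivot")
  mob <- .mobile_block(n, pivot)
  if (length(mob) == 0L || theta == 0) return(chain)
  u <- chain$xyz[pivot + 1L, ] - chain$xyz[pivot, ]
  if (sqrt(sum(u^2)) < 1e-12) stop("degenerate pivot bond")
  R <- .rotation_matrix(u, theta)
  p <- chain$xyz[pivot, ]
  chain$xyz[mob, ] <- sweep(sweep(chain$xyz[mob, , drop = FALSE], 2, p) %*% t(R),
                            2, p, "+")
  for (i in mob) chain$frame[[i]] <- R %*% chain$frame[[i]]
  chain
}

#' Per-residue C-alpha coordinates of a chain
#'
#' Reconstructs one coordinate per residue: coarse sites place their stored
#' member geometry through the site's rigid-body frame; plain sites map to
#' their own position. For a never-coarse-grained chain this is the site
#' coordinate matrix itself.
#'
#' @param chain A \code{coarse_chain}.
#' @return \code{n_res} x 3 matrix of coordinates (nm).
#' @export
expand_to_residues <- function(chain) {
  stopifnot(inherits(chain, "coarse_chain"))
  out <- matrix(NA_real_, chain$n_res, 3)
  colnames(out) <- c("x", "y", "z")
  for (i in seq_len(nrow(chain$xyz))) {
    glob <- chain$local[[i]] %*% t(chain$frame[[i]])
    glob <- sweep(glob, 2, chain$xyz[i, ], "+")
    out[chain$span[i, 1]:chain$span[i, 2], ] <- glob
  }
  if (anyNA(out)) stop("site spans do not tile the residue range")
  out
}

#' Radius of gyration
#'
#' Root-mean-square distance of points from their centroid.
#'
#' @param xyz n x 3 coordinate matrix.
#' @return Scalar, same length unit as the input.
#' @export
radius_of_gyration <- function(xyz) {
  xyz <- as.matrix(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
}

#' @export
print.coarse_chain <- function(x, ...) {
  cat("coarse_chain:", nrow(x$xyz), "site(s) over", x$n_res, "residue(s);",
      sum(x$pivots$frozen), "of", nrow(x$pivots), "pivot(s) frozen\n")
  cat("  total charge:", round(sum(x$q), 3), "e; Rg:",
      round(radius_of_gyration(x$xyz), 3), "nm\n")
  invisible(x)
}
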