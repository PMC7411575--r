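#' Site frequency spectrum counts
#'
#' Container for an observed 1D or joint 2D site frequency spectrum. Counts
#' are stored in a full array indexed from allele count 0 (a vector of length
#' n+1, or an (n1+1) x (n2+1) matrix), so monomorphic cells are carried along;
#' likelihood computations exclude them via [polymorphic_mask()]. When
#' `folded`, mass sits only in canonical minor-allele cells: 1D indices
#' 1..floor(n/2) (plus monomorphic mass at 0); in 2D, of each pair of cells
#' `(i, j)` and `(n1-i, n2-j)` only the one with the smaller total count is
#' populated (fold-boundary cells, where the totals tie, are kept un-doubled).
#' Counts may be real-valued (projection produces expected counts).
#'
#' @param counts numeric vector (1D) or matrix (2D) of non-negative counts
#'   indexed from 0.
#' @param n haploid sample size(s); defaults taken from the array dimensions.
#' @param folded logical flag.
#' @param pops population label(s), one per dimension.
#' @return an object of class `"sfs_counts"`.
#' @export
sfs_counts <- function(counts, n = NULL, folded = FALSE, pops = NULL) {
  if (is.matrix(counts)) {
    if (is.null(n)) n <- dim(counts) - 1L
    stopifnot(length(n) == 2L, all(dim(counts) == n + 1L))
  } else {
    counts <- as.numeric(counts)
    if (is.null(n)) n <- length(counts) - 1L
    stopifnot(length(n) == 1L, length(counts) == n + 1L)
  }
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("SFS counts must be finite and >= 0")
  if (folded && !all(counts[!folded_support(n)] == 0))
    stop("counts outside the canonical folded support of a folded SFS")
  if (is.null(pops)) pops <- paste0("pop", seq_along(n))
  structure(list(n = as.integer(n), counts = counts, folded = folded,
                 pops = pops), class = "sfs_counts")
}

#' @export
print.sfs_counts <- function(x, ...) {
  cat(sprintf("%s %s SFS, n = %s, %s segregating sites\n",
              if (x$folded) "Folded" else "Unfolded",
              if (length(x$n) == 2L) "joint 2D" else "1D",
              paste(x$n, collapse = " x "),
              format(sum(x$counts[polymorphic_mask(x$n, x$folded)]))))
  invisible(x)
}

# cells a folded spectrum may populate (monomorphic mass kept at the
# all-ancestral corner)
folded_support <- function(n) {
  if (length(n) == 1L) {
    i <- 0:n
    i <= n / 2
  } else {
    i <- matrix(0:n[1L], n[1L] + 1L, n[2L] + 1L)
    j <- matrix(0:n[2L], n[1L] + 1L, n[2L] + 1L, byrow = TRUE)
    s <- i + j
    S <- sum(n)
    s < S / 2 | (s == S / 2 & (i < n[1L] - i | (i == n[1L] - i & j <= n[2L] - j)))
  }
}

#' Polymorphic-cell mask
#'
#' Logical array marking the SFS cells that enter composite-likelihood
#' totals: monomorphic cells (all-ancestral, all-derived) are excluded, and
#' for a folded spectrum only canonical minor-allele cells are kept.
#'
#' @param n haploid size(s).
#' @param folded logical.
#' @return logical vector/matrix shaped like the counts array.
#' @export
polymorphic_mask <- function(n, folded) {
  if (length(n) == 1L) {
    i <- 0:n
    keep <- i >= 1L & i <= n - 1L
    if (folded) keep <- keep & i <= n / 2
    keep
  } else {
    i <- matrix(0:n[1L], n[1L] + 1L, n[2L] + 1L)
    j <- matrix(0:n[2L], n[1L] + 1L, n[2L] + 1L, byrow = TRUE)
    s <- i + j
    keep <- s >= 1L & s <= sum(n) - 1L
    if (folded) keep <- keep & folded_support(n)
    keep
  }
}

# core folding of a full counts array (shared by fold_sfs and expected_sfs)
fold_array <- function(counts, n) {
  if (length(n) == 1L) {
    # entry k (k < n/2) = c[k] + c[n-k]; the middle class is kept once
    out <- numeric(n + 1L)
    for (k in 0:floor(n / 2)) {
      out[k + 1L] <- counts[k + 1L] + if (k != n - k) counts[n - k + 1L] else 0
    }
    out
  } else {
    keep <- folded_support(n)
    out <- counts * 0
    for (i in 0:n[1L]) for (j in 0:n[2L]) {
      ii <- i + 1L; jj <- j + 1L
      if (keep[ii, jj]) {
        mi <- n[1L] - i + 1L; mj <- n[2L] - j + 1L
        self <- (mi == ii && mj == jj)
        out[ii, jj] <- counts[ii, jj] + if (self) 0 else counts[mi, mj]
      }
    }
    out
  }
}

#' Fold a site frequency spectrum by minor allele
#'
#' 1D: folded entry i = unfolded_i + unfolded_(n-i) for i < n/2, with the
#' middle class (i = n/2, n even) kept un-doubled. 2D: cells are combined
#' with their complement `(n1-i, n2-j)` by total minor-allele count across
#' both populations; fold-boundary cells (total exactly half) are kept once.
#' Total count (including monomorphic mass) is preserved.
#'
#' @param x an unfolded [sfs_counts()].
#' @return a folded `sfs_counts`.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs_counts"))
  if (x$folded) stop("SFS is already folded")
  sfs_counts(fold_array(x$counts, x$n), n = x$n, folded = TRUE, pops = x$pops)
}

#' Project an SFS to a smaller sample size
#'
#' Hypergeometric downsampling: output entry j is `sum_i input_i * P(j of to
#' | i of n)` with `P` the hypergeometric probability of drawing j derived
#' alleles in a subsample of size `to` (per dimension, independently, for 2D).
#' Mass landing in monomorphic cells is retained in the array but excluded
#' from polymorphic totals; projecting to the current size is the identity.
#'
#' @param x an unfolded [sfs_counts()].
#' @param to target haploid size(s), `2 <= to <= n` per dimension.
#' @return projected `sfs_counts` (real-valued expected counts).
#' @export
project_sfs <- function(x, to) {
  stopifnot(inherits(x, "sfs_counts"))
  if (x$folded) stop("project an unfolded SFS, then fold")
  to <- as.integer(to)
  if (length(to) != length(x$n)) stop("`to` must match the SFS dimension")
  if (any(to < 2L)) stop("projection size must be >= 2 per dimension")
  if (any(to > x$n)) stop("cannot project up: to > n")
  proj_mat <- function(n, t) {
    # P[j+1, i+1] = P(j of t | i derived of n)
    outer(0:t, 0:n, function(j, i) dhyper(j, i, n - i, t))
  }
  if (length(x$n) == 1L) {
    out <- as.numeric(proj_mat(x$n, to) %*% x$counts)
  } else {
    out <- proj_mat(x$n[1L], to[1L]) %*% x$counts %*%
      t(proj_mat(x$n[2L], to[2L]))
  }
  sfs_counts(out, n = to, folded = FALSE, pops = x$pops)
}

#' Build an observed SFS from a genotype panel
#'
#' Tallies, per site, the alternate-allele count among non-missing genotypes
#' in the requested population(s). Without projection only sites fully
#' genotyped in those populations contribute (counts must share a common
#' sample size); with `project_to`, each site's contribution is spread over
#' the projected counts by the hypergeometric expectation and sites whose
#' non-missing haploid count falls below the projection size are dropped --
#' the standard treatment of missing data in reduced-representation panels.
#' The result is folded by minor allele (totalled across populations for a
#' joint spectrum) unless `fold = FALSE`.
#'
#' @param panel a [genotype_panel()].
#' @param populations one or two population labels, or a named list of one or
#'   two character vectors of population labels to pool into groups.
#' @param project_to optional haploid projection size(s), one per group.
#' @param fold fold the result (default TRUE).
#' @return an [sfs_counts()].
#' @export
sfs_from_panel <- function(panel, populations, project_to = NULL, fold = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.list(populations))
    populations <- setNames(as.list(populations), populations)
  stopifnot(length(populations) %in% 1:2)
  pop <- panel$individuals$population
  members <- lapply(populations, function(ps) {
    miss <- setdiff(ps, unique(pop))
    if (length(miss)) stop("unknown population(s): ", paste(miss, collapse = ", "))
    which(pop %in% ps)
  })
  n_full <- vapply(members, function(i) 2L * length(i), integer(1))
  two_d <- length(members) == 2L
  if (!is.null(project_to)) {
    project_to <- as.integer(project_to)
    stopifnot(length(project_to) == length(members))
    if (any(project_to > n_full))
      stop("project_to exceeds available haploid counts (",
           paste(n_full, collapse = ", "), ")")
    if (any(project_to < 2L)) stop("project_to must be >= 2")
  }

  G <- panel$geno
  alt <- lapply(members, function(i) colSums(G[i, , drop = FALSE], na.rm = TRUE))
  nmiss <- lapply(members, function(i) 2L * colSums(!is.na(G[i, , drop = FALSE])))

  if (is.null(project_to)) {
    ok <- Reduce(`&`, Map(function(h, nf) h == nf, nmiss, n_full))
    n_out <- n_full
    if (two_d) {
      counts <- matrix(0, n_out[1L] + 1L, n_out[2L] + 1L)
      if (any(ok)) {
        tab <- table(factor(alt[[1L]][ok], levels = 0:n_out[1L]),
                     factor(alt[[2L]][ok], levels = 0:n_out[2L]))
        counts <- counts + unclass(tab)
      }
    } else {
      counts <- as.numeric(table(factor(alt[[1L]][ok], levels = 0:n_out[1L])))
    }
  } else {
    ok <- Reduce(`&`, Map(function(h, p) h >= p, nmiss, project_to))
    n_out <- project_to
    if (two_d) {
      counts <- matrix(0, n_out[1L] + 1L, n_out[2L] + 1L)
      for (s in which(ok)) {
        w1 <- dhyper(0:n_out[1L], alt[[1L]][s], nmiss[[1L]][s] - alt[[1L]][s],
                     n_out[1L])
        w2 <- dhyper(0:n_out[2L], alt[[2L]][s], nmiss[[2L]][s] - alt[[2L]][s],
                     n_out[2L])
        counts <- counts + outer(w1, w2)
      }
    } else {
      counts <- numeric(n_out + 1L)
      for (s in which(ok)) {
        counts <- counts + dhyper(0:n_out, alt[[1L]][s],
                                  nmiss[[1L]][s] - alt[[1L]][s], n_out)
      }
    }
  }
  x <- sfs_counts(counts, n = n_out, folded = FALSE, pops = names(populations))
  if (fold) fold_sfs(x) else x
}

#' Read and write the plain-text SFS format
#'
#' Line 1 holds the haploid size(s) and the flag `FOLDED` or `UNFOLDED`;
#' the counts follow, monomorphic cells included: one line of n+1 numbers for
#' a 1D spectrum, or n1+1 lines of n2+1 numbers for a joint spectrum. The
#' round trip is bit-stable (counts serialized at full double precision).
#'
#' @param x an [sfs_counts()].
#' @param path file path.
#' @return `write_sfs` returns `path` invisibly; `read_sfs` an `sfs_counts`.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs_counts"))
  hdr <- paste(c(x$n, if (x$folded) "FOLDED" else "UNFOLDED"), collapse = " ")
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- if (length(x$n) == 2L) {
    c(hdr, apply(x$counts, 1L, fmt))
  } else c(hdr, fmt(x$counts))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  folded <- toupper(hdr[length(hdr)]) == "FOLDED"
  if (!toupper(hdr[length(hdr)]) %in% c("FOLDED", "UNFOLDED"))
    stop("malformed SFS header: ", lines[1L])
  n <- as.integer(hdr[-length(hdr)])
  body <- lapply(lines[-1L][nzchar(trimws(lines[-1L]))], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  counts <- if (length(n) == 2L) do.call(rbind, body) else body[[1L]]
  sfs_counts(counts, n = n, folded = folded)
}
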