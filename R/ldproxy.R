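#' Restrict a genotype matrix to rare variants
#'
#' A variant is rare when its minor allele frequency is at most `maf_max`
#' (boundary inclusive) and positive. Order is preserved. An empty result is
#' returned (not an error) when nothing survives; the end-to-end test then
#' reports p = 1 with a reason code.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_max MAF threshold, default 0.04.
#' @return a `genotype_matrix` of the surviving variants (possibly with zero
#'   columns).
#' @export
rare_filter <- function(gm, maf_max = 0.04) {
  stopifnot(inherits(gm, "genotype_matrix"), maf_max > 0, maf_max <= 0.5)
  subset_variants(gm, gm$maf > 0 & gm$maf <= maf_max)
}

#' Pairwise squared correlation of dose vectors
#'
#' Squared Pearson correlation between variant dose columns, the r-squared
#' used to decide linkage-disequilibrium grouping. Missing doses are handled
#' by pairwise deletion. r-squared is invariant to allele-coding flips.
#'
#' @param gm a `genotype_matrix` with at least two variants.
#' @return symmetric matrix in [0, 1] with unit diagonal.
#' @export
pairwise_r2 <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- ncol(gm$counts)
  if (m < 2L) stop("need at least two variants for pairwise r2")
  sds <- apply(gm$counts, 2L, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    stop("constant dose column: ", gm$variants$id[which(sds == 0 | is.na(sds))[1L]])
  r <- suppressWarnings(cor(gm$counts, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[is.na(r2)] <- 0  # pairs with no joint variation after deletion
  diag(r2) <- 1
  dimnames(r2) <- list(gm$variants$id, gm$variants$id)
  r2
}

#' Single-link LD groups
#'
#' Groups variants so that every member has squared correlation strictly
#' greater than `threshold` with at least one other member of its group:
#' the connected components of the graph with edges r2 > threshold
#' (single-link clustering). Deterministic and independent of variant order.
#'
#' @param r2 symmetric matrix from [pairwise_r2()].
#' @param threshold linking threshold, default 0.9; the boundary value does
#'   not link.
#' @return list of integer vectors partitioning `1:ncol(r2)`, each sorted,
#'   ordered by their smallest member.
#' @export
single_link_groups <- function(r2, threshold = 0.9) {
  m <- ncol(r2)
  if (is.null(m) || m != nrow(r2)) stop("r2 must be a square matrix")
  if (m == 0L) return(list())
  # union-find over edges r2 > threshold
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (!is.na(r2[i, j]) && r2[i, j] > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1L))
  groups <- split(seq_len(m), roots)
  groups <- lapply(groups, sort)
  names(groups) <- NULL
  groups[order(vapply(groups, min, integer(1L)))]
}

#' Collapse LD groups to proxy variants
#'
#' Each group's proxy dose for a subject is the maximum rare-allele count
#' over the group's members (0, 1 or 2), taken over non-missing doses. A
#' singleton group's proxy equals the variant itself.
#'
#' @param gm a `genotype_matrix` (the rare-filtered set that was clustered).
#' @param partition list of index vectors from [single_link_groups()].
#' @param r2_threshold threshold recorded alongside the proxies.
#' @return An object of class `proxy_set`: list with `proxies` (subjects x
#'   groups dose matrix), `groups` (the partition), `r2_threshold`.
#' @export
make_proxies <- function(gm, partition, r2_threshold = 0.9) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- ncol(gm$counts)
  idx <- sort(unlist(partition))
  if (!identical(as.integer(idx), seq_len(m)))
    stop("partition must cover every variant exactly once")
  P <- vapply(partition, function(members) {
    block <- gm$counts[, members, drop = FALSE]
    out <- suppressWarnings(apply(block, 1L, max, na.rm = TRUE))
    out[!is.finite(out)] <- NA_real_  # all members missing for that subject
    out
  }, numeric(nrow(gm$counts)))
  P <- matrix(P, nrow = nrow(gm$counts))
  rownames(P) <- gm$subjects
  colnames(P) <- vapply(partition, function(g) gm$variants$id[g[1L]],
                        character(1L))
  structure(list(proxies = P, groups = partition,
                 r2_threshold = r2_threshold),
            class = "proxy_set")
}

#' @exportS3Method base::print
print.proxy_set <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("proxy_set:", length(x$groups), "proxy variants from",
      sum(sizes), "rare variants (r2 >", x$r2_threshold, ")\n")
  if (any(sizes > 1L))
    cat("  ", sum(sizes > 1L), "group(s) with >1 member; largest:",
        max(sizes), "\n")
  invisible(x)
}

# full clustering stage: rare gm -> proxy_set
cluster_proxies <- function(gm_rare, r2_threshold = 0.9) {
  m <- ncol(gm_rare$counts)
  if (m == 0L) {
    return(structure(list(proxies = matrix(numeric(0),
                                           nrow = nrow(gm_rare$counts)),
                          groups = list(), r2_threshold = r2_threshold),
                     class = "proxy_set"))
  }
  if (m == 1L) {
    return(make_proxies(gm_rare, list(1L), r2_threshold))
  }
  r2 <- pairwise_r2(gm_rare)
  make_proxies(gm_rare, single_link_groups(r2, r2_threshold), r2_threshold)
}
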