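#' Offspring-parent pair set
#'
#' Builds one weighted pair per (offspring, phenotyped parent): an
#' offspring with two phenotyped parents contributes two pairs, each with
#' weight 1 (no midparent averaging).  The dependent value `y` is the
#' offspring's adjusted phenotype, the independent value `x` the parent's.
#' `cluster_id` labels the offspring's nuclear family (shared parental
#' links), so both of an offspring's pairs - and its full siblings' pairs -
#' form one resampling unit for the cluster bootstrap.
#'
#' @param adjusted [compute_adjusted()] output.
#' @param table the [pedigree_table()] the adjusted values came from.
#' @param parent_cohort,offspring_cohort optional cohort filters for
#'   per-generation analyses; `NULL` keeps all resolvable pairs.
#' @return A `pair_set` data.frame (`kind = "OP"`) with columns
#'   `dependent_id`, `independent_id`, `y`, `x`, `weight`, `cluster_id`.
#' @export
build_op_pairs <- function(adjusted, table, parent_cohort = NULL,
                           offspring_cohort = NULL) {
  stopifnot(inherits(adjusted, "adjusted_phenotypes"))
  adj <- as.data.frame(adjusted)
  value <- setNames(adj$adjusted_value, adj$individual_id)
  cohort <- setNames(adj$cohort_id, adj$individual_id)

  off <- adj
  if (!is.null(offspring_cohort)) {
    off <- off[off$cohort_id %in% offspring_cohort, , drop = FALSE]
  }
  one <- function(parent_col) {
    pid <- off[[parent_col]]
    keep <- !is.na(pid) & pid %in% names(value)
    if (!is.null(parent_cohort)) {
      keep <- keep & cohort[pid] %in% parent_cohort
      keep[is.na(keep)] <- FALSE
    }
    data.frame(dependent_id = off$individual_id[keep],
               independent_id = pid[keep],
               y = off$adjusted_value[keep],
               x = unname(value[pid[keep]]),
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(one("father_id"), one("mother_id"))
  if (nrow(pairs) == 0) {
    stop("no resolvable offspring-parent pairs", call. = FALSE)
  }
  fam_key <- paste(ifelse(is.na(off$father_id), "", off$father_id),
                   ifelse(is.na(off$mother_id), "", off$mother_id),
                   sep = "|")
  pairs$weight <- 1
  pairs$cluster_id <- fam_key[match(pairs$dependent_id, off$individual_id)]
  pairs <- pairs[order(pairs$dependent_id, pairs$independent_id,
                       method = "radix"), ]
  rownames(pairs) <- NULL
  n_unpaired <- sum(!off$individual_id %in% pairs$dependent_id &
                      (!is.na(off$father_id) | !is.na(off$mother_id)))
  structure(pairs, kind = "OP", n_unpaired = n_unpaired,
            class = c("pair_set", "data.frame"))
}

#' Full-sib pair set with k(k-1) weighting
#'
#' For each sibship of size `k >= 2` (among individuals with adjusted
#' values), forms all `k(k-1)` ordered pairs (each sibling once as
#' dependent against every co-sibling as independent) and assigns each
#' pair weight `1/(k-1)`, so every sibling contributes total
#' dependent-side weight 1 and sibships are weighted by size `k`, not
#' `k(k-1)`.  Singleton sibships contribute nothing.  `cluster_id` is the
#' sibship id.
#'
#' @inheritParams build_op_pairs
#' @param cohort optional cohort filter on the siblings.
#' @return A `pair_set` data.frame (`kind = "FS"`).
#' @export
build_fs_pairs <- function(adjusted, table, cohort = NULL) {
  stopifnot(inherits(adjusted, "adjusted_phenotypes"))
  adj <- as.data.frame(adjusted)
  sib <- adj[!is.na(adj$sibship_id), , drop = FALSE]
  if (!is.null(cohort)) sib <- sib[sib$cohort_id %in% cohort, , drop = FALSE]
  sib <- sib[order(sib$sibship_id, sib$individual_id, method = "radix"), ]
  k <- table(sib$sibship_id)
  sib <- sib[sib$sibship_id %in% names(k[k >= 2]), , drop = FALSE]
  if (nrow(sib) == 0) {
    stop("no sibships of size >= 2 with adjusted phenotypes", call. = FALSE)
  }
  sib_rle <- rle(sib$sibship_id)
  ksz <- sib_rle$lengths
  start <- cumsum(c(0L, ksz[-length(ksz)]))
  # all ordered within-sibship (dep, ind) index pairs, vectorized over groups
  k_rep <- rep.int(ksz, ksz^2)
  cell <- sequence(ksz^2) - 1L
  dep_loc <- cell %/% k_rep
  ind_loc <- cell %% k_rep
  keep_cell <- dep_loc != ind_loc
  g_start <- rep.int(start, ksz^2)[keep_cell]
  dep <- g_start + dep_loc[keep_cell] + 1L
  ind <- g_start + ind_loc[keep_cell] + 1L
  pairs <- data.frame(dependent_id = sib$individual_id[dep],
                      independent_id = sib$individual_id[ind],
                      y = sib$adjusted_value[dep],
                      x = sib$adjusted_value[ind],
                      weight = 1 / (rep.int(ksz, ksz^2)[keep_cell] - 1),
                      cluster_id = sib$sibship_id[dep],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$dependent_id, pairs$independent_id,
                       method = "radix"), ]
  rownames(pairs) <- NULL
  structure(pairs, kind = "FS",
            n_sibs = nrow(sib), n_sibships = length(ksz),
            class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set> kind=", attr(x, "kind"), ", ", nrow(x), " pairs, ",
      length(unique(x$cluster_id)), " clusters\n", sep = "")
  if (identical(attr(x, "kind"), "FS")) {
    cat(attr(x, "n_sibs"), " siblings in ", attr(x, "n_sibships"),
        " sibships of size >= 2\n", sep = "")
  }
  invisible(x)
}

#' Spouse correlation of adjusted phenotypes
#'
#' Couples are identified through shared offspring: every distinct
#' (father_id, mother_id) combination appearing on some individual's
#' parental links, with both members phenotyped, contributes one
#' observation.  Returns the Pearson correlation of the two spouses'
#' adjusted values, used downstream to correct heritability for
#' assortative mating.
#'
#' @inheritParams build_op_pairs
#' @param cohort optional cohort filter on the parents.
#' @return List with `r`, large-sample `se` (`sqrt((1 - r^2)/(n - 2))`),
#'   and `n_couples`.
#' @export
spouse_correlation <- function(adjusted, table, cohort = NULL) {
  stopifnot(inherits(adjusted, "adjusted_phenotypes"))
  adj <- as.data.frame(adjusted)
  value <- setNames(adj$adjusted_value, adj$individual_id)
  couples <- unique(adj[!is.na(adj$father_id) & !is.na(adj$mother_id),
                        c("father_id", "mother_id")])
  keep <- couples$father_id %in% names(value) &
    couples$mother_id %in% names(value)
  couples <- couples[keep, , drop = FALSE]
  if (!is.null(cohort)) {
    ch <- setNames(adj$cohort_id, adj$individual_id)
    couples <- couples[ch[couples$father_id] %in% cohort &
                         ch[couples$mother_id] %in% cohort, , drop = FALSE]
  }
  n <- nrow(couples)
  if (n < 3) {
    stop("insufficient data: fewer than 3 phenotyped couples", call. = FALSE)
  }
  r <- stats::cor(value[couples$father_id], value[couples$mother_id])
  list(r = unname(r), se = sqrt((1 - r^2) / (n - 2)), n_couples = n)
}

#' Write a pair set as TSV
#'
#' @param pairs a `pair_set`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_set"))
  out <- cbind(kind = attr(pairs, "kind"), as.data.frame(pairs))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
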