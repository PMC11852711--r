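# Sequence-motif aptamer families: single-linkage clustering by shared
# substrings of a minimum length, and most-abundant representatives.

#' Longest common substring of two sequences
#'
#' Classic dynamic program; returns the (first, leftmost in `a`) longest
#' contiguous substring shared by `a` and `b` and its length.
#'
#' @param a,b Character scalars.
#' @return A list with `substring` and `length`.
#' @export
longest_common_substring <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  if (length(x) == 0L || length(y) == 0L) return(list(substring = "", length = 0L))
  best_len <- 0L
  best_end <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match_j <- which(y == x[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best_len) {
        best_len <- cur[j]
        best_end <- i
      }
    }
    prev <- cur
  }
  list(substring = substr(a, best_end - best_len + 1L, best_end),
       length = best_len)
}

#' Cluster aptamers into sequence-motif families
#'
#' Two aptamers are linked when they share an exact substring of at least
#' `min_motif_length` nt; families are the connected components of the link
#' graph (single linkage, i.e. the transitive closure of the sharing
#' relation). Clustering must be run on variable regions only: constant
#' primer flanks would trivially link everything. Sequences shorter than the
#' threshold become singletons by construction. Family ids are canonical
#' (named after the lexicographically smallest member id) so the result is
#' invariant to input order.
#'
#' @param sequences Named character vector (aptamer id -> variable-region
#'   sequence) over the A/C/G/T alphabet.
#' @param min_motif_length Minimal shared substring length (default 12,
#'   must be >= 8).
#' @return An object of class `aptamer_families`: `assignments` (data frame
#'   `aptamer_id`, `family_id`) and `families` (data frame `family_id`,
#'   `n_members`, `motif` — a longest shared substring over the family's
#'   links, NA for singletons).
#' @export
cluster_families <- function(sequences, min_motif_length = 12L) {
  if (length(sequences) < 1L || is.null(names(sequences))) {
    stopf("sequences must be a non-empty named vector")
  }
  min_motif_length <- as.integer(min_motif_length)
  if (min_motif_length < 8L) stopf("min_motif_length must be >= 8")
  sequences <- vapply(sequences, normalize_sequence, character(1))
  check_dna_alphabet(sequences)
  ids <- names(sequences)
  if (anyDuplicated(ids)) stopf("duplicate aptamer id: %s", ids[duplicated(ids)][1])
  n <- length(ids)
  k <- min_motif_length

  # sequences share a substring of length >= k iff they share a k-mer
  kmer_owner <- list()
  for (i in seq_len(n)) {
    for (km in seq_kmers(sequences[i], k)) {
      kmer_owner[[km]] <- c(kmer_owner[[km]], i)
    }
  }
  edges <- list()
  for (owners in kmer_owner) {
    if (length(owners) > 1L) {
      pairs <- utils::combn(owners, 2L)
      edges[[length(edges) + 1L]] <- t(pairs)
    }
  }
  if (length(edges)) {
    em <- unique(do.call(rbind, edges))
    g <- igraph::graph_from_edgelist(
      matrix(as.character(em), ncol = 2L), directed = FALSE)
    g <- igraph::add_vertices(
      g, length(setdiff(as.character(seq_len(n)), igraph::V(g)$name)),
      name = setdiff(as.character(seq_len(n)), igraph::V(g)$name))
    comp <- igraph::components(g)$membership
    membership <- integer(n)
    membership[as.integer(names(comp))] <- comp
  } else {
    em <- matrix(integer(0), ncol = 2L)
    membership <- seq_len(n)
  }

  # canonical labels: family named after its lexicographically smallest member
  fam_ids <- character(n)
  motif_of_comp <- character(0)
  for (m in unique(membership)) {
    members <- which(membership == m)
    label <- sprintf("fam_%s", min(ids[members]))
    fam_ids[members] <- label
    if (length(members) > 1L) {
      # witness: longest common substring over the component's links
      link_rows <- which(membership[em[, 1L]] == m)
      best <- list(substring = NA_character_, length = -1L)
      for (r in link_rows) {
        lcs <- longest_common_substring(sequences[em[r, 1L]], sequences[em[r, 2L]])
        if (lcs$length > best$length) best <- lcs
      }
      motif_of_comp[label] <- best$substring
    } else {
      motif_of_comp[label] <- NA_character_
    }
  }

  ord <- order(ids)
  assignments <- data.frame(aptamer_id = ids[ord], family_id = fam_ids[ord],
                            stringsAsFactors = FALSE)
  fam_tab <- as.data.frame(table(assignments$family_id), stringsAsFactors = FALSE)
  names(fam_tab) <- c("family_id", "n_members")
  fam_tab <- fam_tab[order(fam_tab$family_id), , drop = FALSE]
  fam_tab$motif <- unname(motif_of_comp[fam_tab$family_id])
  rownames(fam_tab) <- NULL
  structure(list(assignments = assignments, families = fam_tab,
                 min_motif_length = min_motif_length),
            class = "aptamer_families")
}

#' @export
print.aptamer_families <- function(x, ...) {
  multi <- x$families$n_members > 1L
  cat(sprintf("aptamer_families: %d aptamers in %d families (%d multi-member, %d singletons) at motif >= %d nt\n",
              nrow(x$assignments), nrow(x$families), sum(multi), sum(!multi),
              x$min_motif_length))
  invisible(x)
}

#' Pick the most abundant representative per family
#'
#' The representative is the member with the maximal total count across all
#' samples; ties resolve to the lexicographically smallest sequence (then
#' smallest id).
#'
#' @param families An [cluster_families()] result.
#' @param x An [apta_counts] containing every clustered aptamer (with
#'   sequences, used for tie-breaking).
#' @return Named character vector: family_id -> representative aptamer_id.
#' @export
select_representatives <- function(families, x) {
  stopifnot(inherits(families, "aptamer_families"), inherits(x, "apta_counts"))
  asg <- families$assignments
  missing <- setdiff(asg$aptamer_id, x$aptamer_ids)
  if (length(missing)) stopf("family member %s missing from count matrix", missing[1])
  totals <- colSums(x$counts)[asg$aptamer_id]
  seqs <- if (!is.null(x$sequences)) x$sequences[asg$aptamer_id] else asg$aptamer_id
  reps <- vapply(split(seq_len(nrow(asg)), asg$family_id), function(idx) {
    o <- order(-totals[idx], seqs[idx], asg$aptamer_id[idx])
    asg$aptamer_id[idx][o[1L]]
  }, character(1))
  reps[order(names(reps))]
}
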