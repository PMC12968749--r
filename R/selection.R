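#' Maturity-group window around a target MG
#'
#' Accessions from the maturity groups immediately adjacent to a target MG
#' can usually still flower and mature normally alongside it, so MG-scoped
#' selection pools the target MG with its earlier and later neighbours. At
#' the boundaries the window is clipped: MG `000` pools only `{000, 00}` and
#' MG `X` only `{IX, X}`.
#'
#' @param target One of [mg_levels]; `UNDETERMINED` is not a valid target.
#' @return An object of class `mg_window`: list with `target` and `members`
#'   (character vector in MG order).
#' @examples
#' mg_window("00")   # 000, 00, 0
#' mg_window("X")    # IX, X
#' @export
mg_window <- function(target) {
  if (identical(target, mg_undetermined)) {
    abort_fmt("cannot build an MG window around UNDETERMINED")
  }
  idx <- match(target, mg_levels)
  if (is.na(idx)) abort_fmt("unknown maturity group: %s", target)
  members <- mg_levels[max(1L, idx - 1L):min(length(mg_levels), idx + 1L)]
  structure(list(target = target, members = members), class = "mg_window")
}

#' @export
print.mg_window <- function(x, ...) {
  cat(sprintf("MG window %s: {%s}\n", x$target, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Build a diverse set: one accession per cluster
#'
#' Draws the diverse set (DS) from a cluster assignment: within each cluster
#' the user-preferred member is taken if present and not excluded; otherwise
#' one member is drawn uniformly at random (seeded) among non-excluded,
#' seed-available members. Clusters with no eligible member are reported as
#' exhausted rather than silently back-filled from other clusters, so the
#' one-per-cluster diversity guarantee is never diluted.
#'
#' @param A A `cluster_assignment` from [kmeans_cluster()].
#' @param meta Optional accession metadata ([accession_meta()]); when `NULL`
#'   every accession is treated as seed-available.
#' @param preferred,excluded Character vectors of accession ids; must be
#'   disjoint, and at most one preferred accession per cluster.
#' @param seed Integer seed for the random picks.
#' @return An object of class `diverse_set`: list with `picks` (data frame of
#'   `cluster`, `accession_id`, `mode` in random/preferred/replacement),
#'   `exhausted` (integer cluster labels), `k` and `seed`.
#' @export
build_diverse_set <- function(A, meta = NULL, preferred = character(),
                              excluded = character(), seed = 1) {
  stopifnot(inherits(A, "cluster_assignment"))
  preferred <- as.character(preferred)
  excluded <- as.character(excluded)
  both <- intersect(preferred, excluded)
  if (length(both)) {
    abort_fmt("accession %s is both preferred and excluded", both[1L])
  }
  ids <- names(A$labels)
  avail <- availability_of(ids, meta)
  pref_lab <- A$labels[intersect(preferred, ids)]
  if (anyDuplicated(pref_lab)) {
    abort_fmt("cluster %d contains more than one preferred accession",
              pref_lab[duplicated(pref_lab)][1L])
  }
  picks <- list()
  exhausted <- integer(0)
  for (lab in 0:(A$k - 1L)) {
    members <- ids[A$labels == lab]
    pref <- setdiff(intersect(members, preferred), excluded)
    if (length(pref)) {
      picks[[length(picks) + 1L]] <- data.frame(
        cluster = lab, accession_id = pref[1L], mode = "preferred",
        stringsAsFactors = FALSE)
      next
    }
    eligible <- sort(setdiff(members[avail[members]], excluded))
    if (!length(eligible)) {
      exhausted <- c(exhausted, lab)
      next
    }
    set.seed(derive_seed(seed, 211, lab))
    pick <- eligible[sample.int(length(eligible), 1L)]
    picks[[length(picks) + 1L]] <- data.frame(
      cluster = lab, accession_id = pick, mode = "random",
      stringsAsFactors = FALSE)
  }
  picks <- if (length(picks)) do.call(rbind, picks) else
    data.frame(cluster = integer(0), accession_id = character(0),
               mode = character(0), stringsAsFactors = FALSE)
  structure(list(picks = picks, exhausted = exhausted, k = A$k, seed = seed),
            class = "diverse_set")
}

availability_of <- function(ids, meta) {
  if (is.null(meta)) {
    avail <- rep(TRUE, length(ids))
  } else {
    idx <- match(ids, meta$accession_id)
    if (anyNA(idx)) abort_fmt("metadata is missing accession: %s",
                              ids[is.na(idx)][1L])
    avail <- meta$seed_available[idx]
  }
  names(avail) <- ids
  avail
}

#' Replace picks that turned out unusable
#'
#' When a selected accession later proves unusable (seed fails to germinate,
#' accession withdrawn), another member of the same cluster is drawn as a
#' replacement. Unaffected picks are left untouched.
#'
#' @param ds A `diverse_set`.
#' @param A The `cluster_assignment` it was built from.
#' @param meta Optional accession metadata.
#' @param excluded Accession ids now excluded (typically including earlier
#'   picks).
#' @param seed Integer seed for the replacement draws.
#' @return The updated `diverse_set`; replaced picks carry mode
#'   `"replacement"`, clusters with no remaining eligible member move to
#'   `exhausted`.
#' @export
replace_picks <- function(ds, A, meta = NULL, excluded = character(), seed = 1) {
  stopifnot(inherits(ds, "diverse_set"), inherits(A, "cluster_assignment"))
  excluded <- as.character(excluded)
  ids <- names(A$labels)
  avail <- availability_of(ids, meta)
  picks <- ds$picks
  drop_rows <- integer(0)
  for (i in seq_len(nrow(picks))) {
    if (!picks$accession_id[i] %in% excluded) next
    lab <- picks$cluster[i]
    members <- ids[A$labels == lab]
    eligible <- sort(setdiff(members[avail[members]], excluded))
    if (!length(eligible)) {
      drop_rows <- c(drop_rows, i)
      ds$exhausted <- sort(c(ds$exhausted, lab))
      next
    }
    set.seed(derive_seed(seed, 223, lab))
    picks$accession_id[i] <- eligible[sample.int(length(eligible), 1L)]
    picks$mode[i] <- "replacement"
  }
  if (length(drop_rows)) picks <- picks[-drop_rows, , drop = FALSE]
  ds$picks <- picks
  ds
}

#' @export
print.diverse_set <- function(x, ...) {
  cat(sprintf("diverse_set: %d picks from k = %d clusters (seed %d)\n",
              nrow(x$picks), x$k, x$seed))
  tb <- table(x$picks$mode)
  cat(sprintf("  modes: %s; exhausted clusters: %d\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              length(x$exhausted)))
  invisible(x)
}

#' Draw a random set of accessions
#'
#' The unstratified baseline: a uniform sample without replacement. The
#' draw depends only on the id set (ids are sorted before sampling), not on
#' their input order.
#'
#' @param accession_ids Character vector of ids to sample from.
#' @param n Sample size, `1 <= n <= length(accession_ids)`.
#' @param seed Integer seed.
#' @return Character vector of `n` accession ids.
#' @export
build_random_set <- function(accession_ids, n, seed = 1) {
  ids <- sort(as.character(accession_ids))
  check_scalar_number(n, "n", min = 1)
  if (n != round(n) || n > length(ids)) {
    abort_fmt("`n` must be an integer in [1, %d]", length(ids))
  }
  set.seed(derive_seed(seed, 307))
  ids[sample.int(length(ids), n)]
}

#' Export a diverse-set selector table
#'
#' Clusters the whole collection, and optionally each maturity-group window,
#' at every requested k, and emits a single table with one cluster-label
#' column per (scope, k) combination. Sorting any column groups similar
#' accessions together so one pick per cluster can be made by hand;
#' accessions outside a column's MG window get an empty cell. Columns whose
#' k exceeds the scope's accession count are skipped with a warning while
#' the remaining columns are still emitted.
#'
#' @param G A [genotype_matrix()].
#' @param meta Accession metadata; `UNDETERMINED`-MG accessions appear in
#'   whole-collection columns but are excluded from every MG-scoped column.
#' @param k_list Integer vector of cluster counts.
#' @param mg_targets Character vector of target MGs (possibly empty).
#' @param seed Integer seed propagated to every clustering run.
#' @param path Optional CSV output path.
#' @param het_het Heterozygote rule passed to [pairwise_distance()].
#' @return The selector table (data frame), invisibly when written.
#' @export
export_selector_table <- function(G, meta = NULL, k_list, mg_targets = character(),
                                  seed = 1, path = NULL, het_het = 1) {
  if (!length(k_list)) abort_fmt("`k_list` must be non-empty")
  ids <- rownames(G)
  if (is.null(meta)) meta <- accession_meta(ids)
  meta <- meta[match(ids, meta$accession_id), , drop = FALSE]
  if (anyNA(meta$accession_id)) {
    abort_fmt("metadata is missing accession: %s", ids[is.na(meta$accession_id)][1L])
  }
  tab <- data.frame(accession_id = ids, species = meta$species,
                    maturity_group = meta$maturity_group,
                    stringsAsFactors = FALSE)
  scopes <- list(list(name = "all", ids = ids))
  for (t in mg_targets) {
    w <- mg_window(t)
    in_w <- meta$maturity_group %in% w$members
    scopes[[length(scopes) + 1L]] <- list(name = sprintf("MG_%s", t),
                                          ids = ids[in_w])
  }
  for (sc in scopes) {
    if (!length(sc$ids)) {
      warning(sprintf("scope %s has no accessions; skipped", sc$name),
              call. = FALSE)
      next
    }
    Dsc <- pairwise_distance(G[sc$ids, ], het_het = het_het)
    for (k in k_list) {
      col <- sprintf("%s_k%d", sc$name, k)
      if (k > length(sc$ids)) {
        warning(sprintf("column %s skipped: k = %d exceeds %d accessions",
                        col, k, length(sc$ids)), call. = FALSE)
        next
      }
      A <- kmeans_cluster(Dsc, k, seed = derive_seed(seed, 401, k))
      tab[[col]] <- NA_integer_
      tab[[col]][match(sc$ids, ids)] <- unname(A$labels[sc$ids])
    }
  }
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}
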