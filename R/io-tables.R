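#' Construct or validate an accession metadata table
#'
#' Accession metadata carries what the genotype files cannot: species,
#' maturity group (MG), whether the accession is a user-preferred pick, and
#' whether seed is available for distribution.
#'
#' @param accession_id Character vector of unique ids.
#' @param species `"max"` (cultivated) or `"soja"` (wild).
#' @param maturity_group One of [mg_levels] or `"UNDETERMINED"`.
#' @param preferred,seed_available Logical flags.
#' @return A `data.frame` with the five validated columns.
#' @export
accession_meta <- function(accession_id, species = "max",
                           maturity_group = "UNDETERMINED",
                           preferred = FALSE, seed_available = TRUE) {
  n <- length(accession_id)
  accession_id <- as.character(accession_id)
  if (anyDuplicated(accession_id)) {
    abort_fmt("duplicate accession id in metadata: %s",
              accession_id[duplicated(accession_id)][1L])
  }
  meta <- data.frame(accession_id = accession_id,
                     species = rep_len(as.character(species), n),
                     maturity_group = rep_len(as.character(maturity_group), n),
                     preferred = rep_len(as.logical(preferred), n),
                     seed_available = rep_len(as.logical(seed_available), n),
                     stringsAsFactors = FALSE)
  bad <- setdiff(meta$species, c("max", "soja"))
  if (length(bad)) abort_fmt("unknown species label: %s", bad[1L])
  bad <- setdiff(meta$maturity_group, c(mg_levels, mg_undetermined))
  if (length(bad)) abort_fmt("unknown maturity group: %s", bad[1L])
  meta
}

#' Read / write accession metadata CSV
#'
#' Comma-delimited UTF-8 with a header row and columns `accession_id`,
#' `species`, `maturity_group`, `preferred`, `seed_available`.
#'
#' @param path File path.
#' @return For the reader, a validated metadata `data.frame`.
#' @export
read_accession_meta <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("accession_id", "species", "maturity_group",
            "preferred", "seed_available")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort_fmt("metadata file lacks column(s): %s",
                              paste(miss, collapse = ", "))
  accession_meta(tab$accession_id, tab$species, tab$maturity_group,
                 as.logical(tab$preferred), as.logical(tab$seed_available))
}

#' @rdname read_accession_meta
#' @param meta A metadata `data.frame` as from [accession_meta()].
#' @export
write_accession_meta <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(meta)
}

#' Write a cluster table
#'
#' One row per accession, with metadata columns first and one cluster-label
#' column per assignment. Sorting any cluster column groups equal labels
#' together, which is how users pick one accession per cluster by eye or
#' spreadsheet.
#'
#' @param assignments A list of [kmeans_cluster()] results, all over the same
#'   accession set. Names become column headers; unnamed entries get
#'   `k<k>` headers.
#' @param meta Accession metadata covering at least the clustered accessions;
#'   may be `NULL`, in which case species/MG columns are filled with
#'   `UNDETERMINED` defaults.
#' @param path Output CSV path, or `NULL` to just return the table.
#' @return The table, invisibly when written.
#' @export
write_cluster_table <- function(assignments, meta = NULL, path = NULL) {
  if (length(assignments)) {
    idsets <- lapply(assignments, function(a) sort(names(a$labels)))
    if (!all(vapply(idsets, identical, logical(1L), y = idsets[[1L]]))) {
      abort_fmt("assignments cover different accession sets")
    }
    ids <- names(assignments[[1L]]$labels)
  } else {
    if (is.null(meta)) abort_fmt("need at least one assignment or metadata")
    ids <- meta$accession_id
  }
  if (is.null(meta)) meta <- accession_meta(ids)
  meta <- meta[match(ids, meta$accession_id), , drop = FALSE]
  if (anyNA(meta$accession_id)) {
    abort_fmt("metadata is missing accession: %s", ids[is.na(meta$accession_id)][1L])
  }
  tab <- data.frame(accession_id = ids, species = meta$species,
                    maturity_group = meta$maturity_group,
                    stringsAsFactors = FALSE)
  nm <- names(assignments) %||% rep("", length(assignments))
  for (i in seq_along(assignments)) {
    a <- assignments[[i]]
    col <- if (nzchar(nm[i])) nm[i] else sprintf("k%d", a$k)
    tab[[col]] <- unname(a$labels[ids])
  }
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(accession_id = "character",
                          maturity_group = "character"))
}

#' Persist a distance matrix as CSV
#'
#' Either a square matrix with accession ids as header and first column, or a
#' long-form pair list with columns `id_a`, `id_b`, `distance`, `n_loci`
#' (unordered pairs, upper triangle).
#'
#' @param D An `ibs_dist` object from [pairwise_distance()].
#' @param path Output path.
#' @param format `"square"` or `"pairs"`.
#' @export
write_distance <- function(D, path, format = c("square", "pairs")) {
  format <- match.arg(format)
  if (format == "square") {
    tab <- data.frame(accession_id = D$accession_ids, D$d,
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- c("accession_id", D$accession_ids)
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(upper.tri(D$d), arr.ind = TRUE)
    tab <- data.frame(id_a = D$accession_ids[idx[, 1L]],
                      id_b = D$accession_ids[idx[, 2L]],
                      distance = D$d[idx],
                      n_loci = D$n_loci[idx],
                      stringsAsFactors = FALSE)
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(D)
}
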