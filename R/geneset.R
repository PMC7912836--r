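#' Recognized geneset provenance labels
#'
#' The seven annotation sources from which cilia- and ciliopathy-associated
#' gene lists are drawn: the two UniProtKB/Swiss-Prot queries, the 100,000
#' Genomes Project panels, and the four compiled public cilia libraries.
#'
#' @format Character vector of length 7.
#' @export
CILIA_SOURCES <- c(
  "uniprot_cilia", "uniprot_ciliopathy", "genomes100k",
  "centrosomedb", "cildb", "syscilia", "ciliacarta"
)

new_gene_set <- function(symbol, uniprot_id, name, sources, is_ciliopathy,
                         label = "cilia geneset") {
  stopifnot(is.list(sources), length(symbol) == length(sources))
  df <- data.frame(
    symbol = as.character(symbol),
    uniprot_id = as.character(uniprot_id),
    name = as.character(name),
    is_ciliopathy = as.logical(is_ciliopathy),
    stringsAsFactors = FALSE
  )
  df$sources <- sources
  if (anyDuplicated(df$symbol)) stop("duplicate symbols in gene set")
  if (any(!nzchar(df$symbol))) stop("empty symbol in gene set")
  if (nrow(df) && any(lengths(df$sources) < 1L)) {
    stop("every gene record needs at least one provenance source")
  }
  structure(df, class = c("gene_set", "data.frame"), label = label)
}

#' Merge labelled gene-identifier lists into one deduplicated geneset
#'
#' Combines per-source gene lists into a single geneset keyed by normalized
#' gene symbol (trimmed, uppercased). Each record keeps the union of
#' contributing source labels; a gene is flagged `is_ciliopathy` exactly when
#' at least one of its sources is a ciliopathy-labelled source. Records are
#' returned in lexicographic symbol order.
#'
#' @param source_lists Named list; each element is a `data.frame` with columns
#'   `symbol`, `accession`, `name` (extra columns ignored), and the element
#'   name is its provenance label, one of [CILIA_SOURCES].
#' @param ciliopathy_sources Character vector of source labels whose member
#'   genes are flagged ciliopathy-associated.
#' @param label Free-text label for the merged set.
#'
#' @return A `gene_set`: a `data.frame` with columns `symbol`, `uniprot_id`,
#'   `name`, `is_ciliopathy` and a list-column `sources`, plus a `label`
#'   attribute.
#'
#' @details Entries with an empty symbol are dropped with a warning. When two
#'   sources give different accessions for one symbol the first seen (in input
#'   order) is kept and the conflict is reported as a warning.
#'
#' @examples
#' merge_gene_sources(list(
#'   uniprot_cilia = data.frame(symbol = c("FOXJ1", "NEK6"),
#'                              accession = c("Q92949", "Q9HC98"),
#'                              name = c("Forkhead box J1", "NIMA kinase 6")),
#'   uniprot_ciliopathy = data.frame(symbol = "BBS9", accession = "Q3SYG4",
#'                                   name = "Bardet-Biedl syndrome 9")
#' ))
#' @export
merge_gene_sources <- function(source_lists,
                               ciliopathy_sources = "uniprot_ciliopathy",
                               label = "cilia geneset") {
  stopifnot(is.list(source_lists))
  labs <- names(source_lists)
  if (length(source_lists)) {
    if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs))) {
      stop("each source list must be named with its provenance label")
    }
    bad <- setdiff(labs, CILIA_SOURCES)
    if (length(bad)) {
      stop("unrecognized source label(s): ", paste(bad, collapse = ", "))
    }
  }
  long <- do.call(rbind, lapply(labs, function(lab) {
    x <- source_lists[[lab]]
    stopifnot(is.data.frame(x), "symbol" %in% names(x))
    data.frame(
      source = rep(lab, nrow(x)),
      symbol = toupper(trimws(as.character(x$symbol))),
      accession = if ("accession" %in% names(x)) {
        as.character(x$accession)
      } else {
        rep(NA_character_, nrow(x))
      },
      name = if ("name" %in% names(x)) {
        as.character(x$name)
      } else {
        rep(NA_character_, nrow(x))
      },
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(long) || nrow(long) == 0L) {
    return(new_gene_set(character(), character(), character(), list(),
                        logical(), label = label))
  }
  empty <- is.na(long$symbol) | !nzchar(long$symbol)
  if (any(empty)) {
    warning(sum(empty), " entr", if (sum(empty) == 1L) "y" else "ies",
            " with empty symbol rejected")
    long <- long[!empty, , drop = FALSE]
  }
  syms <- sort_c(unique(long$symbol))
  idx <- split(seq_len(nrow(long)), factor(long$symbol, levels = syms))
  pick_first <- function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (length(v)) v else NA_character_
  }
  uniprot <- character(length(syms))
  nm <- character(length(syms))
  srcs <- vector("list", length(syms))
  for (i in seq_along(syms)) {
    rows <- long[idx[[i]], , drop = FALSE]
    accs <- unique(rows$accession[!is.na(rows$accession) &
                                    nzchar(rows$accession)])
    if (length(accs) > 1L) {
      warning("conflicting accessions for ", syms[i], " (",
              paste(accs, collapse = ", "), "); keeping first seen")
    }
    uniprot[i] <- pick_first(rows$accession)[1L]
    nm[i] <- pick_first(rows$name)[1L]
    srcs[[i]] <- sort_c(unique(rows$source))
  }
  is_cilio <- vapply(srcs, function(s) any(s %in% ciliopathy_sources),
                     logical(1))
  new_gene_set(syms, uniprot, nm, srcs, is_cilio, label = label)
}

#' Restrict a geneset to genes detected in a compartment's datasets
#'
#' The compartment geneset is the subset of the merged geneset whose symbols
#' are measured on at least one platform of the compartment, i.e. appear in
#' the gene list of one or more of the compartment's expression datasets.
#'
#' @param gs A `gene_set`.
#' @param datasets List of [expression_dataset()] objects; all must share one
#'   compartment label.
#' @param label Optional label; defaults to `"<compartment> cilia geneset"`.
#' @return A `gene_set` that is a subset of `gs`.
#' @export
compartment_geneset <- function(gs, datasets, label = NULL) {
  stopifnot(inherits(gs, "gene_set"), length(datasets) >= 1L)
  comps <- unique(vapply(datasets, function(d) d$compartment, character(1)))
  if (length(comps) != 1L) {
    stop("datasets mix compartments: ", paste(comps, collapse = ", "))
  }
  present <- unique(unlist(lapply(datasets, function(d) rownames(d$values))))
  keep <- gs$symbol %in% present
  new_gene_set(gs$symbol[keep], gs$uniprot_id[keep], gs$name[keep],
               gs$sources[keep], gs$is_ciliopathy[keep],
               label = label %||% paste(comps, "cilia geneset"))
}

#' Summarize a geneset
#'
#' @param gs A `gene_set`.
#' @return List with `total`, `n_ciliopathy` and `per_source_counts` (named
#'   integer vector of how many records cite each source).
#' @export
geneset_summary <- function(gs) {
  stopifnot(inherits(gs, "gene_set"))
  tab <- table(unlist(gs$sources))
  per_source <- stats::setNames(as.integer(tab), names(tab))
  list(
    total = nrow(gs),
    n_ciliopathy = sum(gs$is_ciliopathy),
    per_source_counts = as.list(per_source[sort_c(names(per_source))])
  )
}

#' Split a merged geneset back into per-source lists
#'
#' Inverse-direction view of [merge_gene_sources()]: one `data.frame`
#' (`symbol`, `accession`, `name`) per provenance label. Re-merging the result
#' reproduces the original geneset.
#'
#' @param gs A `gene_set`.
#' @return Named list of `data.frame`s keyed by source label.
#' @export
as_source_lists <- function(gs) {
  stopifnot(inherits(gs, "gene_set"))
  labs <- sort_c(unique(unlist(gs$sources)))
  out <- lapply(labs, function(lab) {
    keep <- vapply(gs$sources, function(s) lab %in% s, logical(1))
    data.frame(symbol = gs$symbol[keep], accession = gs$uniprot_id[keep],
               name = gs$name[keep], stringsAsFactors = FALSE)
  })
  stats::setNames(out, labs)
}

#' Read labelled source lists from a TSV file
#'
#' The file carries one entry per row with header
#' `source<TAB>symbol<TAB>accession<TAB>name`; a single file may mix several
#' sources.
#'
#' @param path Path to the TSV file.
#' @return Named list of `data.frame`s, one per source label, in file order.
#' @export
read_source_lists <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("source", "symbol")
  if (!all(need %in% names(x))) {
    stop("source list file needs columns: ", paste(need, collapse = ", "))
  }
  if (!"accession" %in% names(x)) x$accession <- NA_character_
  if (!"name" %in% names(x)) x$name <- NA_character_
  labs <- unique(x$source)
  out <- lapply(labs, function(lab) {
    x[x$source == lab, c("symbol", "accession", "name"), drop = FALSE]
  })
  stats::setNames(out, labs)
}

#' Write / read a merged geneset as TSV
#'
#' Columns: `symbol`, `uniprot_id`, `name`, `sources` (semicolon-joined) and
#' `is_ciliopathy` (0/1).
#'
#' @param gs A `gene_set`.
#' @param path Output (or input) TSV path.
#' @return `write_geneset()` returns `path` invisibly; `read_geneset()`
#'   returns a `gene_set`.
#' @export
write_geneset <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  out <- data.frame(
    symbol = gs$symbol,
    uniprot_id = ifelse(is.na(gs$uniprot_id), "", gs$uniprot_id),
    name = ifelse(is.na(gs$name), "", gs$name),
    sources = vapply(gs$sources, paste, character(1), collapse = ";"),
    is_ciliopathy = as.integer(gs$is_ciliopathy),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geneset
#' @param label Label for the geneset read back from disk.
#' @export
read_geneset <- function(path, label = "cilia geneset") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("symbol", "sources", "is_ciliopathy")
  if (!all(need %in% names(x))) {
    stop("geneset file needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(x$uniprot_id)) x$uniprot_id <- rep("", nrow(x))
  if (is.null(x$name)) x$name <- rep("", nrow(x))
  new_gene_set(
    x$symbol,
    ifelse(nzchar(x$uniprot_id), x$uniprot_id, NA_character_),
    ifelse(nzchar(x$name), x$name, NA_character_),
    strsplit(x$sources, ";", fixed = TRUE),
    as.integer(x$is_ciliopathy) == 1L,
    label = label
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes (%d ciliopathy-flagged)\n",
              attr(x, "label") %||% "", nrow(x), sum(x$is_ciliopathy)))
  invisible(x)
}
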