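#' Test whether two phoneme sequences are phonological neighbors
#'
#' Two words are phonological neighbors when exactly one addition,
#' deletion, or substitution of a single phoneme turns one into the other,
#' i.e. when the phoneme-level Levenshtein distance is exactly 1.
#' Identical sequences (distance 0) are not neighbors.
#'
#' @param a,b Character vectors of phoneme symbols.
#' @return Logical scalar.
#' @examples
#' is_phon_neighbor(c("k", "a", "t"), c("a", "t"))   # deletion
#' is_phon_neighbor(c("k", "a", "t"), c("k", "a", "t")) # identical: FALSE
#' @export
is_phon_neighbor <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) stop("phoneme sequences must be non-empty")
  dl <- la - lb
  if (abs(dl) > 1L) return(FALSE)
  if (dl == 0L) return(sum(a != b) == 1L)
  # lengths differ by one: check that deleting one phoneme from the longer
  # sequence yields the shorter one
  long <- if (dl > 0L) a else b
  short <- if (dl > 0L) b else a
  n <- length(short)
  i <- 1L
  while (i <= n && long[i] == short[i]) i <- i + 1L
  # first mismatch at i (or none): skip long[i], rest must match
  if (i > n) return(TRUE) # short is a prefix of long
  all(long[(i + 1L):(n + 1L)] == short[i:n])
}

# Encode phoneme sequences as single-character-per-phoneme strings so that
# neighbor detection can use substring hashing. Inventories are mapped to
# consecutive Unicode code points starting above the control range.
encode_words <- function(phonemes) {
  inv <- sort(unique(unlist(phonemes, use.names = FALSE)))
  codes <- vapply(seq_along(inv), function(i) intToUtf8(160L + i), "")
  names(codes) <- inv
  vapply(phonemes, function(p) paste(codes[p], collapse = ""), "")
}

# All index pairs (i < j) of words at phoneme edit distance exactly 1.
# Substitutions are found by grouping words on "length:prefix*suffix" keys;
# additions/deletions by matching single-phoneme deletions of the longer
# word against the full shorter word. O(total length) expected, versus the
# naive all-pairs scan.
find_edit1_pairs <- function(words) {
  n <- length(words)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  lens <- nchar(words)
  maxlen <- max(lens)
  ei <- vector("list", 2L * maxlen)
  k <- 0L
  word_index <- split(seq_len(n), words)
  for (p in seq_len(maxlen)) {
    idx <- which(lens >= p)
    if (length(idx) == 0L) next
    pre <- substr(words[idx], 1L, p - 1L)
    post <- substr(words[idx], p + 1L, lens[idx])
    # substitution: same length, agree everywhere except position p
    key <- paste0(lens[idx], "\r", pre, "\r", post)
    grp <- split(seq_along(idx), key)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp)) {
      subpairs <- lapply(grp, function(g) {
        ch <- substr(words[idx[g]], p, p)
        pr <- utils::combn(seq_along(g), 2L)
        keep <- ch[pr[1L, ]] != ch[pr[2L, ]] # equal => identical words
        if (!any(keep)) return(NULL)
        cbind(idx[g][pr[1L, keep]], idx[g][pr[2L, keep]])
      })
      subpairs <- do.call(rbind, subpairs)
      if (!is.null(subpairs) && nrow(subpairs)) {
        k <- k + 1L
        ei[[k]] <- subpairs
      }
    }
    # deletion at position p of words with length >= 2
    del_idx <- idx[lens[idx] >= 2L]
    if (length(del_idx)) {
      del <- paste0(substr(words[del_idx], 1L, p - 1L),
                    substr(words[del_idx], p + 1L, lens[del_idx]))
      hits <- word_index[del]
      hl <- lengths(hits)
      if (any(hl > 0L)) {
        src <- rep.int(del_idx, hl)
        dst <- unlist(hits, use.names = FALSE)
        k <- k + 1L
        ei[[k]] <- cbind(src, dst)
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2L))
  pairs <- do.call(rbind, ei[seq_len(k)])
  lo <- pmin(pairs[, 1L], pairs[, 2L])
  hi <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- !duplicated(lo * (n + 1) + hi)
  cbind(lo[keep], hi[keep])
}

#' Build the phonological network of a lexicon
#'
#' Creates an undirected simple graph with one node per lexicon entry and
#' an edge between every pair of words at phoneme edit distance exactly 1
#' (one addition, deletion, or substitution). Words with no neighbors
#' remain in the graph as isolates; homophones (identical transcriptions)
#' stay distinct nodes with no edge between them. The edge set is
#' deterministic for a given lexicon, independent of entry order.
#'
#' @param lexicon A `phon_lexicon`.
#' @return An [igraph::igraph] with vertex attributes `name` (the
#'   `word_id`) and `transcription`.
#' @export
build_phon_network <- function(lexicon) {
  stopifnot(inherits(lexicon, "phon_lexicon"))
  words <- encode_words(lexicon$phonemes)
  pairs <- find_edit1_pairs(words)
  g <- igraph::make_empty_graph(n = nrow(lexicon$entries), directed = FALSE)
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, as.vector(t(pairs)))
  }
  igraph::V(g)$name <- lexicon$entries$word_id
  igraph::V(g)$transcription <- lexicon$entries$transcription
  g
}

#' Write a network to disk
#'
#' Supported formats: `"graphml"`, `"gml"`, `"pajek"`, and `"edgelist"`.
#' All formats preserve isolated nodes and node identifiers on round-trip:
#' the edge-list format, which by itself lists only connected nodes, is
#' written together with a node manifest file (`<path>.nodes`) carrying
#' the full vertex set.
#'
#' @param network An igraph with a `name` vertex attribute.
#' @param path Output path.
#' @param format One of `"graphml"`, `"gml"`, `"pajek"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "gml", "pajek", "edgelist")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(network))
  if (is.null(igraph::V(network)$name)) {
    igraph::V(network)$name <- as.character(seq_len(igraph::vcount(network)))
  }
  if (format == "edgelist") {
    el <- igraph::as_edgelist(network, names = TRUE)
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
    writeLines(igraph::V(network)$name, paste0(path, ".nodes"))
  } else if (format == "pajek") {
    igraph::V(network)$id <- igraph::V(network)$name # pajek writer labels from 'id'
    igraph::write_graph(network, path, format = "pajek")
  } else {
    igraph::write_graph(network, path, format = format)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to the file.
#' @param format One of `"graphml"`, `"gml"`, `"pajek"`, `"edgelist"`.
#' @return An igraph with vertex `name`s restored.
#' @export
read_network <- function(path,
                         format = c("graphml", "gml", "pajek", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  if (format == "edgelist") {
    manifest <- paste0(path, ".nodes")
    if (!file.exists(manifest)) {
      stop(sprintf("node manifest not found: %s", manifest))
    }
    nodes <- readLines(manifest, warn = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      el <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
      g <- igraph::add_edges(g, t(matrix(match(el, nodes), ncol = 2L)))
    }
    return(g)
  }
  g <- igraph::read_graph(path, format = format)
  g <- igraph::as_undirected(g, mode = "collapse")
  attrs <- igraph::vertex_attr_names(g)
  if (!("name" %in% attrs) && "id" %in% attrs) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  g
}
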