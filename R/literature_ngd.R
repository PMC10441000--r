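#' Concept-to-publication map
#'
#' Holds, for each biomedical concept, the set of PubMed-style publication
#' identifiers annotated to it, plus the corpus-level normalizer `N` (total
#' number of term-pair annotations in the corpus) used by the normalized
#' Google distance.
#'
#' @param pubs named list: concept id -> character vector of publication ids
#'   (deduplicated on construction).
#' @param total_pairs corpus normalizer `N`; must be at least the largest
#'   single-concept publication count.
#' @return An object of class `concept_pub_map`.
#' @export
concept_pub_map <- function(pubs, total_pairs) {
  stopifnot(is.list(pubs), length(names(pubs)) == length(pubs))
  pubs <- lapply(pubs, function(p) unique(as.character(p)))
  counts <- lengths(pubs)
  if (total_pairs < max(c(counts, 1L)))
    stop("total_pairs must be >= the largest single-concept count")
  structure(list(pubs = pubs, total_pairs = as.numeric(total_pairs)),
            class = "concept_pub_map")
}

#' Read a long-format concept/publication TSV
#'
#' Expects columns `concept_id`, `publication_id` and a header comment line
#' `#total_pairs=N` carrying the corpus normalizer.
#'
#' @param path TSV path.
#' @return A [concept_pub_map()].
#' @export
read_concept_pubs <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#total_pairs=", first))
    stop("missing '#total_pairs=N' header comment in ", path)
  total <- as.numeric(sub("^#total_pairs=", "", first))
  dt <- fread(path, sep = "\t", skip = 1L, colClasses = "character")
  concept_pub_map(split(dt$publication_id, dt$concept_id), total)
}

#' Write a concept-publication map as TSV
#' @param m a `concept_pub_map`.
#' @param path output path.
#' @export
write_concept_pubs <- function(m, path) {
  dt <- data.table(concept_id = rep(names(m$pubs), lengths(m$pubs)),
                   publication_id = unlist(m$pubs, use.names = FALSE))
  writeLines(sprintf("#total_pairs=%.0f", m$total_pairs), path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Publication co-occurrence count of two concepts
#' @param m a `concept_pub_map`.
#' @param c1,c2 concept ids; concepts absent from the map count as zero.
#' @return integer count of shared publication ids.
#' @export
cooccurrence <- function(m, c1, c2)
  length(intersect(m$pubs[[c1]], m$pubs[[c2]]))

#' Normalized Google distance between two concepts
#'
#' With \eqn{\mathcal{N}(c)} the number of publications annotated to concept
#' \eqn{c}, \eqn{\mathcal{N}(c_1,c_2)} the shared count and \eqn{N} the corpus
#' normalizer,
#' \deqn{NGD = \frac{\max(\log \mathcal{N}(c_1), \log \mathcal{N}(c_2)) -
#'   \log \mathcal{N}(c_1,c_2)}{\log N -
#'   \min(\log \mathcal{N}(c_1), \log \mathcal{N}(c_2))}.}
#' The value is symmetric and invariant to the base of the logarithm.  A
#' zero co-occurrence yields `Inf`; a concept with zero publications is a
#' domain error.
#'
#' @param m a `concept_pub_map`.
#' @param c1,c2 concept ids.
#' @return non-negative numeric, possibly `Inf`.
#' @export
ngd <- function(m, c1, c2) {
  n1 <- length(m$pubs[[c1]]); n2 <- length(m$pubs[[c2]])
  if (n1 == 0L || n2 == 0L)
    stop("NGD undefined for a concept with zero publications: ",
         if (n1 == 0L) c1 else c2)
  n12 <- cooccurrence(m, c1, c2)
  if (n12 == 0L) return(Inf)
  (max(log(n1), log(n2)) - log(n12)) /
    (log(m$total_pairs) - min(log(n1), log(n2)))
}

#' Literature-support filter for labeled drug-disease pairs
#'
#' Keeps a pair iff its endpoints share at least `min_cooccur` publications
#' AND their NGD is at most `max_ngd` (both boundaries inclusive).  Pairs
#' with an endpoint absent from the map are treated as zero co-occurrence
#' and dropped.  Intended for literature-mined (e.g. NLP-extracted) label
#' sources, where publication bias and extraction errors call for
#' co-occurrence support; the caller chooses which sources to filter.
#'
#' @param m a `concept_pub_map`.
#' @param pairs data.frame with columns `drug`, `disease` (extra columns
#'   pass through).
#' @param min_cooccur minimum shared-publication count (default 10).
#' @param max_ngd maximum NGD (default 0.6).
#' @return the kept subset of `pairs`, with an `audit` attribute: a
#'   data.table of per-pair `cooccur`, `ngd` and `kept`.
#' @export
literature_filter <- function(m, pairs, min_cooccur = 10, max_ngd = 0.6) {
  pairs <- as.data.table(pairs)
  n <- nrow(pairs)
  co <- numeric(n); nd <- numeric(n)
  for (i in seq_len(n)) {
    d <- pairs$drug[i]; z <- pairs$disease[i]
    if (is.null(m$pubs[[d]]) || is.null(m$pubs[[z]]) ||
        length(m$pubs[[d]]) == 0L || length(m$pubs[[z]]) == 0L) {
      co[i] <- 0; nd[i] <- Inf
    } else {
      co[i] <- cooccurrence(m, d, z)
      nd[i] <- if (co[i] == 0) Inf else ngd(m, d, z)
    }
  }
  kept <- co >= min_cooccur & nd <= max_ngd
  audit <- data.table(drug = pairs$drug, disease = pairs$disease,
                      cooccur = co, ngd = nd, kept = kept)
  out <- pairs[kept]
  setattr(out, "audit", audit)
  out
}
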