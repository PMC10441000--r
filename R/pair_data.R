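#' Merge labeled drug-disease pairs from multiple sources
#'
#' Pairs identical across sources are unioned (their source names merged);
#' a pair labeled `treat` by one source and `not_treat` by another is
#' dropped entirely and reported in the `conflicts` attribute.  Output pairs
#' are unique on `(drug, disease)`.
#'
#' @param sources named list of data.frames, each with columns `drug`,
#'   `disease`, `label` where label is `treat` or `not_treat`.
#' @return data.table with columns `drug`, `disease`, `label`, `sources`
#'   (comma-joined source names) and `split` (`"unassigned"`); attribute
#'   `conflicts` holds the dropped conflicting pairs.
#' @export
merge_labeled_sources <- function(sources) {
  stopifnot(is.list(sources), length(names(sources)) == length(sources))
  all <- rbindlist(lapply(names(sources), function(nm) {
    dt <- as.data.table(sources[[nm]])
    stopifnot(all(c("drug", "disease", "label") %in% names(dt)))
    if (!all(dt$label %in% c("treat", "not_treat")))
      stop("source '", nm, "' contains labels other than treat/not_treat")
    unique(dt[, .(drug, disease, label, src = nm)])
  }))
  merged <- all[, .(labels = list(unique(label)),
                    sources = paste(sort(unique(src)), collapse = ",")),
                by = .(drug, disease)]
  conflict <- lengths(merged$labels) > 1L
  conflicts <- merged[conflict, .(drug, disease, sources)]
  if (nrow(conflicts))
    message(sprintf("dropping %d pair(s) with conflicting labels",
                    nrow(conflicts)))
  out <- merged[!conflict,
                .(drug, disease, label = vapply(labels, `[`, "", 1L),
                  sources, split = "unassigned")]
  setorder(out, drug, disease)
  setattr(out, "conflicts", conflicts)
  out[]
}

#' Negative-sample "unknown"-class pairs
#'
#' For each unique `treat` pair, emits one drug-replaced and one
#' disease-replaced pair, resampling (up to `max_attempts` times) until the
#' candidate appears in neither the treat nor the not-treat class.  Output
#' is deduplicated and labeled `unknown`.
#'
#' @param positives data.frame of treat pairs (`drug`, `disease`).
#' @param known data.frame of all known treat and not-treat pairs.
#' @param drug_ids,disease_ids replacement pools (length >= 2).
#' @param seed integer RNG seed.
#' @param max_attempts bounded resampling per replacement (default 100).
#' @return data.table `drug`, `disease`, `label = "unknown"`.
#' @export
sample_unknown_pairs <- function(positives, known, drug_ids, disease_ids,
                                 seed, max_attempts = 100L) {
  stopifnot(length(drug_ids) >= 2L, length(disease_ids) >= 2L)
  positives <- unique(as.data.table(positives)[, .(drug, disease)])
  known_keys <- paste(known$drug, known$disease, sep = "\r")
  set.seed(seed)
  res <- vector("list", 2L * nrow(positives))
  k <- 0L
  for (i in seq_len(nrow(positives))) {
    d <- positives$drug[i]; z <- positives$disease[i]
    for (side in c("drug", "disease")) {
      pool <- if (side == "drug") drug_ids else disease_ids
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        r <- sample(pool, 1L)
        cand <- if (side == "drug") c(r, z) else c(d, r)
        if (!(paste(cand[1], cand[2], sep = "\r") %in% known_keys)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not sample an unknown pair after ", max_attempts,
             " attempts (", side, " replacement of ", d, "/", z, ")")
      k <- k + 1L
      res[[k]] <- data.table(drug = cand[1], disease = cand[2])
    }
  }
  out <- unique(rbindlist(res))
  out[, label := "unknown"]
  out[]
}

#' Per-drug train/validation/test split
#'
#' Within each drug's group of pairs, pairs are shuffled and assigned so the
#' realized counts are the largest-remainder rounding of the ratios with
#' train-priority on ties.  A drug with a single pair goes entirely to
#' train; a drug with two pairs contributes one to train and one to test.
#' This guarantees every drug seen at validation/test time is also seen in
#' training.
#'
#' @param pairs data.frame with `drug`, `disease` (and any other columns);
#'   the `split` column must be absent or `"unassigned"`.
#' @param ratios train/val/test proportions summing to 1 (default 8/1/1).
#' @param seed integer RNG seed.
#' @return copy of `pairs` with `split` set to train/val/test.
#' @export
split_by_drug <- function(pairs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9)
  pairs <- as.data.table(pairs)
  if ("split" %in% names(pairs) && any(pairs$split != "unassigned"))
    stop("pairs already carry split assignments")
  pairs <- copy(pairs)
  pairs[, split := NA_character_]
  set.seed(seed)
  setorder(pairs, drug, disease)   # canonical order before shuffling
  for (d in unique(pairs$drug)) {
    idx <- which(pairs$drug == d)
    n <- length(idx)
    counts <- if (n == 1L) c(1L, 0L, 0L)
              else if (n == 2L) c(1L, 0L, 1L)
              else largest_remainder(n, ratios)
    lab <- rep(c("train", "val", "test"), counts)
    pairs[idx[sample.int(n)], split := lab]
  }
  pairs[]
}

# largest-remainder apportionment of n into 3 buckets; ties and remainder
# allocation prefer train, then val, then test
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(ratios))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Read / write labeled pair TSV files
#'
#' Columns: `drug`, `disease`, `label`, and optionally `sources`, `split`.
#' @param path TSV path.
#' @return data.table of pairs.
#' @export
read_pairs <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("drug", "disease", "label") %in% names(dt)))
  dt
}

#' @rdname read_pairs
#' @param pairs data.frame of pairs.
#' @export
write_pairs <- function(pairs, path) {
  fwrite(as.data.table(pairs), path, sep = "\t")
  invisible(path)
}

#' Validate that pair endpoints exist in the graph's drug/disease sets
#' @param pairs data.frame with `drug`, `disease`.
#' @param g a `knowledge_graph`.
#' @return invisibly TRUE; errors listing offenders otherwise.
#' @export
validate_pairs <- function(pairs, g) {
  ns <- kg_node_sets(g)
  bad_d <- setdiff(unique(pairs$drug), ns$drugs)
  bad_z <- setdiff(unique(pairs$disease), ns$diseases)
  if (length(bad_d) || length(bad_z))
    stop("unmapped identifiers - drugs: ",
         paste(utils::head(bad_d, 5), collapse = ", "),
         "; diseases: ", paste(utils::head(bad_z, 5), collapse = ", "))
  invisible(TRUE)
}
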