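# Dataset handling: reading IC50 tables, curation, activity labeling and
# stratified splitting.

#' Read a molecule table from CSV
#'
#' Expects a header with a `smiles` column plus `ic50_nm` and/or `log_ic50`
#' (an optional `label` and `id` are kept). Missing ids are generated from
#' row numbers.
#'
#' @param path CSV file path
#' @return data.frame of raw molecule records
#' @export
read_molecule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV must contain a 'smiles' column: ", path)
  if (!any(c("ic50_nm", "log_ic50") %in% names(df)))
    stop("CSV must contain an 'ic50_nm' or 'log_ic50' column: ", path)
  if (!"id" %in% names(df)) df$id <- sprintf("mol_%05d", seq_len(nrow(df)))
  df
}

#' Convert a log10 IC50 (nM) value to a binary activity label
#'
#' Compounds with logIC50 below 2 (IC50 under 100 nM) are active (1); values
#' of exactly 2 or above are inactive (0).
#'
#' @param log_ic50 numeric vector of log10 IC50 values in nM
#' @return integer vector of 0/1 labels
#' @examples
#' binarize_label(c(1.5, 2.5, 2.0))  # 1 0 0
#' @export
binarize_label <- function(log_ic50) {
  if (!is.numeric(log_ic50) || any(!is.finite(log_ic50)))
    stop("log_ic50 must be finite numeric (no NA/NaN)")
  as.integer(log_ic50 < 2)
}

.canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    error = function(e) "")
  can <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(can) || !nzchar(can)) NA_character_ else can
}

#' Curate a raw molecule table
#'
#' Applies the cleaning pipeline: drops multi-component (salt) records,
#' records without a conclusive numeric IC50, unparseable SMILES, and
#' duplicate chemical structures (first occurrence kept, by canonical
#' SMILES). IC50 values in nM are converted to log10; binary activity labels
#' are (re)derived from the threshold logIC50 = 2. Curation is idempotent.
#'
#' @param records data.frame with columns `smiles` and `ic50_nm` or
#'   `log_ic50` (optional `id`)
#' @return curated data.frame with columns `id`, `smiles`,
#'   `canonical_smiles`, `log_ic50`, `label`; dropped records with reasons in
#'   `attr(, "dropped")`
#' @export
curate_dataset <- function(records) {
  if (nrow(records) == 0L)
    return(structure(data.frame(id = character(0), smiles = character(0),
                                canonical_smiles = character(0),
                                log_ic50 = numeric(0), label = integer(0)),
                     dropped = data.frame(id = character(0), reason = character(0))))
  if (!"id" %in% names(records)) records$id <- sprintf("mol_%05d", seq_len(nrow(records)))
  dropped <- list()
  note <- function(ids, reason) dropped[[length(dropped) + 1L]] <<-
    data.frame(id = ids, reason = reason)

  smiles <- as.character(records$smiles)
  keep <- !is.na(smiles) & nzchar(smiles)
  if (any(!keep)) note(records$id[!keep], "empty_smiles")
  records <- records[keep, , drop = FALSE]

  salts <- grepl(".", records$smiles, fixed = TRUE)
  if (any(salts)) note(records$id[salts], "salt_multicomponent")
  records <- records[!salts, , drop = FALSE]

  if ("log_ic50" %in% names(records)) {
    lic <- suppressWarnings(as.numeric(records$log_ic50))
  } else {
    ic <- suppressWarnings(as.numeric(records$ic50_nm))
    ic[!is.na(ic) & ic <= 0] <- NA
    lic <- log10(ic)
  }
  bad <- !is.finite(lic)
  if (any(bad)) note(records$id[bad], "inconclusive_ic50")
  records <- records[!bad, , drop = FALSE]
  lic <- lic[!bad]

  can <- vapply(as.character(records$smiles), .canonical_smiles, character(1),
                USE.NAMES = FALSE)
  bad <- is.na(can)
  if (any(bad)) note(records$id[bad], "unparseable_smiles")
  records <- records[!bad, , drop = FALSE]
  lic <- lic[!bad]; can <- can[!bad]

  dup <- duplicated(can)
  if (any(dup)) note(records$id[dup], "duplicate_structure")
  records <- records[!dup, , drop = FALSE]
  lic <- lic[!dup]; can <- can[!dup]

  out <- data.frame(id = records$id, smiles = as.character(records$smiles),
                    canonical_smiles = can, log_ic50 = lic,
                    label = binarize_label(lic), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(id = character(0), reason = character(0))
  out
}

#' Stratified train/validation/test split
#'
#' Validation and test sizes are `floor(ratio * N)` with the remainder going
#' to the training split; the class ratio is preserved per split by
#' allocating within each label stratum (largest-remainder rounding). The
#' split is deterministic for a given seed.
#'
#' @param records curated data.frame with a `label` column
#' @param ratios numeric triple (train, validation, test) summing to 1
#' @param seed integer RNG seed
#' @return object of class `dataset_split`: list with `train`, `validation`,
#'   `test` data.frames plus `seed` and `ratios`
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0), abs(sum(ratios) - 1) < 1e-8,
            nrow(records) >= 10L, "label" %in% names(records))
  n <- nrow(records)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  if (n_val == 0L || n_test == 0L)
    stop("split of size 0 for a non-zero ratio; need more records")

  # deterministic within-class shuffling
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  labs <- sort(unique(records$label))
  idx_by_class <- lapply(labs, function(l) sample(which(records$label == l)))
  n_class <- vapply(idx_by_class, length, integer(1))

  alloc <- function(target) {
    base <- floor(target * n_class / n)
    rem <- target - sum(base)
    if (rem > 0) {
      frac <- target * n_class / n - base
      ord <- order(frac, n_class, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    base
  }
  val_c <- alloc(n_val)
  test_c <- alloc(n_test)

  take <- function(counts, offset) {
    unlist(lapply(seq_along(idx_by_class), function(k) {
      if (counts[k] == 0L) return(integer(0))
      idx_by_class[[k]][offset[k] + seq_len(counts[k])]
    }))
  }
  val_idx <- take(val_c, rep(0L, length(labs)))
  test_idx <- take(test_c, val_c)
  train_idx <- setdiff(unlist(idx_by_class), c(val_idx, test_idx))

  structure(list(train = records[sort(train_idx), , drop = FALSE],
                 validation = records[sort(val_idx), , drop = FALSE],
                 test = records[sort(test_idx), , drop = FALSE],
                 seed = seed, ratios = ratios),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split (seed %d): train %d / validation %d / test %d\n",
              x$seed, nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' @param split a `dataset_split`
#' @param path output JSON path
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(list(seed = split$seed, ratios = split$ratios,
                            train = split$train$id,
                            validation = split$validation$id,
                            test = split$test$id),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
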