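#' Read molecules from an SDF (V2000) file with partial charges
#'
#' Atom coordinates come from the atom block; per-atom partial charges are
#' read from a data item (`> <PARTIAL_CHARGES>`, one value per atom, in
#' elementary charge units).  An optional `> <PIC50>` item sets the
#' activity directly, though activities normally come from the separate
#' CSV table (see [read_dataset()]).
#'
#' @param path Path to a multi-record V2000 SDF file.
#' @param charge_field Name of the data item holding partial charges.
#' @return Named list of [molecule()] objects (names are the molecule ids,
#'   taken from the title line of each record).
#' @export
read_sdf <- function(path, charge_field = "PARTIAL_CHARGES") {
  lines <- readLines(path)
  # records are separated by "$$$$"
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) stop("no SDF records ($$$$ terminator) in ", path,
                              call. = FALSE)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mols <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:ends[k]]
    rec <- rec[cumsum(nzchar(trimws(rec)) | seq_along(rec) <= 4) > 0]
    mol <- tryCatch(parse_sdf_record(rec, charge_field),
                    error = function(e) {
                      stop("SDF record ", k, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    mols[[k]] <- mol
  }
  ids <- purrr::map_chr(mols, "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(mols, ids)
}

parse_sdf_record <- function(rec, charge_field) {
  if (length(rec) < 4) stop("truncated record")
  id <- trimws(rec[1])
  if (!nzchar(id)) stop("empty title line (no molecule id)")
  counts <- rec[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1) stop("bad counts line")
  if (length(rec) < 4 + n_atoms) stop("atom block shorter than counts line")
  atom_lines <- rec[5:(4 + n_atoms)]
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  element <- trimws(substr(atom_lines, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("unparsable atom coordinates")
  charges <- sdf_data_item(rec, charge_field)
  if (is.null(charges)) stop("missing <", charge_field, "> data item")
  charges <- as.numeric(charges)
  if (length(charges) != n_atoms || anyNA(charges)) {
    stop("<", charge_field, "> must hold one numeric charge per atom")
  }
  pic50 <- sdf_data_item(rec, "PIC50")
  pic50 <- if (is.null(pic50)) NA_real_ else as.numeric(pic50[1])
  molecule(id,
           tibble::tibble(element = element, x = x, y = y, z = z,
                          charge = charges),
           pic50 = pic50)
}

# values of a "> <NAME>" data item (character vector), or NULL
sdf_data_item <- function(rec, name) {
  hdr <- grep(sprintf("^>.*<%s>", name), rec)
  if (length(hdr) == 0) return(NULL)
  i <- hdr[1] + 1L
  vals <- character(0)
  while (i <= length(rec) && nzchar(trimws(rec[i])) &&
         !startsWith(trimws(rec[i]), ">") && trimws(rec[i]) != "$$$$") {
    vals <- c(vals, strsplit(trimws(rec[i]), "[[:space:]]+")[[1]])
    i <- i + 1L
  }
  vals
}

#' Write molecules to an SDF (V2000) file with partial charges
#'
#' Inverse of [read_sdf()]: charges go into a `> <PARTIAL_CHARGES>` data
#' item and the activity, when present, into `> <PIC50>`.
#'
#' @param molecules List of [molecule()] objects.
#' @param path Output path.
#' @param charge_field Name of the data item holding partial charges.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path, charge_field = "PARTIAL_CHARGES") {
  out <- character(0)
  for (mol in molecules) {
    n <- nrow(mol$atoms)
    rec <- c(
      mol$id, "  espqsar", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element),
      "M  END",
      sprintf(">  <%s>", charge_field),
      sprintf("%.6f", mol$atoms$charge),
      ""
    )
    if (!is.na(mol$pic50)) {
      rec <- c(rec, ">  <PIC50>", sprintf("%.6f", mol$pic50), "")
    }
    out <- c(out, rec, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read molecules from an XYZ file with a charge column
#'
#' Extended-XYZ dialect: per molecule, line 1 is the atom count, line 2 the
#' molecule id, then one line per atom with `element x y z charge`
#' (whitespace-separated, Angstrom and elementary charge units).  Multiple
#' molecules may be concatenated.
#'
#' @param path Path to the file.
#' @return Named list of [molecule()] objects.
#' @export
read_xyzq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 0]
  mols <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1 || i + 1 + n > length(lines) + 0) {
      stop("XYZ record ", rec, ": bad atom count line", call. = FALSE)
    }
    id <- trimws(lines[i + 1])
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < 5)) {
      stop("XYZ record ", rec, " (", id,
           "): each atom line needs element x y z charge", call. = FALSE)
    }
    fields <- do.call(rbind, lapply(parts, `[`, 1:5))
    atoms <- tibble::tibble(
      element = fields[, 1],
      x = as.numeric(fields[, 2]), y = as.numeric(fields[, 3]),
      z = as.numeric(fields[, 4]), charge = as.numeric(fields[, 5])
    )
    mols[[id]] <- molecule(id, atoms)
    i <- i + 2L + n
  }
  if (anyDuplicated(names(mols))) {
    stop("duplicate molecule id(s) in ", path, call. = FALSE)
  }
  mols
}

#' Write molecules to an XYZ-with-charges file
#'
#' @param molecules List of [molecule()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyzq <- function(molecules, path) {
  out <- unlist(lapply(molecules, function(mol) {
    c(sprintf("%d", nrow(mol$atoms)),
      mol$id,
      sprintf("%-3s %14.8f %14.8f %14.8f %12.8f",
              mol$atoms$element, mol$atoms$x, mol$atoms$y, mol$atoms$z,
              mol$atoms$charge))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a structure file plus an activity table into molecules
#'
#' Joins molecules (SDF or XYZ-with-charges, chosen by file extension) with
#' an activity CSV holding columns `id` and `pic50` (an `mw` column, if
#' present, is ignored and recomputed from the atoms).  Activity rows whose
#' id has no structure are dropped with a warning; structures without an
#' activity row keep `pic50 = NA`.  Molecules whose atoms all sit at z = 0
#' are rejected as lacking 3D coordinates (the flat layout of 2D SDF
#' exports).
#'
#' @param structures_path SDF (`.sdf`) or XYZ (`.xyz`) file.
#' @param activities_path CSV with columns `id`, `pic50`.
#' @return Named list of [molecule()] objects with `pic50` filled in.
#' @export
read_dataset <- function(structures_path, activities_path) {
  mols <- if (grepl("\\.sdf$", structures_path, ignore.case = TRUE)) {
    read_sdf(structures_path)
  } else {
    read_xyzq(structures_path)
  }
  flat <- purrr::map_lgl(mols, ~ nrow(.x$atoms) > 3 && all(.x$atoms$z == 0))
  if (any(flat)) {
    stop("molecule(s) lacking 3D coordinates (all z = 0): ",
         paste(names(mols)[flat], collapse = ", "), call. = FALSE)
  }
  act <- readr::read_csv(activities_path, show_col_types = FALSE)
  if (!all(c("id", "pic50") %in% names(act))) {
    stop("activity table needs columns id, pic50", call. = FALSE)
  }
  act$id <- as.character(act$id)
  if (anyDuplicated(act$id)) {
    stop("duplicate id(s) in activity table: ",
         paste(unique(act$id[duplicated(act$id)]), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(act$id, names(mols))
  if (length(orphan) > 0) {
    warning("dropping ", length(orphan),
            " activity row(s) with no matching structure: ",
            paste(orphan, collapse = ", "), call. = FALSE)
    act <- act[!act$id %in% orphan, ]
  }
  for (i in seq_len(nrow(act))) {
    mols[[act$id[i]]]$pic50 <- as.numeric(act$pic50[i])
  }
  mols
}

#' Partition molecules into 50-amu molecular-weight subsets
#'
#' Seven contiguous half-open bins `(250, 300], (300, 350], ..., (550, 600]`
#' by default, with the lower edge 250 included in subset 1 so that no
#' molecular weight in the covered range falls between bins.  Molecules
#' outside the covered range are excluded with a warning (or an error).
#'
#' @param molecules List of [molecule()] objects, or a tibble with columns
#'   `id` and `mw`.
#' @param mw_min,bin_width,n_subsets Bin layout (defaults 250, 50, 7).
#' @param out_of_range `"warn"` (drop with a warning) or `"error"`.
#' @return Tibble with columns `id`, `mw`, `subset` (integer 1..n_subsets).
#' @export
partition_by_mw <- function(molecules, mw_min = 250, bin_width = 50,
                            n_subsets = 7,
                            out_of_range = c("warn", "error")) {
  out_of_range <- match.arg(out_of_range)
  tbl <- if (is.data.frame(molecules)) {
    tibble::as_tibble(molecules[, c("id", "mw")])
  } else {
    molecule_table(molecules)[, c("id", "mw")]
  }
  mw_max <- mw_min + bin_width * n_subsets
  bad <- tbl$mw < mw_min | tbl$mw > mw_max
  if (any(bad)) {
    msg <- paste0(sum(bad), " molecule(s) outside [", mw_min, ", ", mw_max,
                  "] amu: ", paste(tbl$id[bad], collapse = ", "))
    if (out_of_range == "error") stop(msg, call. = FALSE)
    warning("excluding ", msg, call. = FALSE)
    tbl <- tbl[!bad, ]
  }
  # (lo, hi] bins; the global lower edge folds into subset 1
  subset <- ceiling((tbl$mw - mw_min) / bin_width)
  subset[subset < 1] <- 1L
  tbl$subset <- as.integer(subset)
  tbl
}

#' Split each molecular-weight subset into training and test sets
#'
#' A seeded random split, stratified only by subset, at the given ratio
#' (default 4:1, i.e. a 70-member subset yields 56 training and 14 test
#' molecules).  The training count is `ceiling(n * train / (train + test))`.
#'
#' @param partition Tibble from [partition_by_mw()].
#' @param ratio Length-2 integer vector `c(train, test)`, default `c(4, 1)`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return The partition tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_train_test <- function(partition, ratio = c(4, 1), seed) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  if (missing(seed)) stop("a seed is required for a reproducible split",
                          call. = FALSE)
  counts <- table(partition$subset)
  if (any(counts < sum(ratio) / min(ratio))) {
    small <- names(counts)[counts < sum(ratio) / min(ratio)]
    stop("subset(s) ", paste(small, collapse = ", "),
         " too small to honor a ", ratio[1], ":", ratio[2], " split",
         call. = FALSE)
  }
  partition$split <- NA_character_
  with_preserved_seed({
    set.seed(as.integer(seed))
    for (s in sort(unique(partition$subset))) {
      idx <- which(partition$subset == s)
      n <- length(idx)
      n_train <- ceiling(n * ratio[1] / sum(ratio))
      train_idx <- sample(idx, n_train)
      partition$split[idx] <- ifelse(idx %in% train_idx, "train", "test")
    }
  })
  partition
}

#' Select the template molecule of a subset
#'
#' The member with the highest molecular weight; ties are broken by the
#' lexicographically smallest id.
#'
#' @param subset Tibble with columns `id` and `mw` (e.g. one subset of the
#'   [partition_by_mw()] output).
#' @param molecules Named list of [molecule()] objects.
#' @return The template [molecule()].
#' @export
select_template <- function(subset, molecules) {
  if (nrow(subset) == 0) stop("empty subset: no template", call. = FALSE)
  ord <- order(-subset$mw, subset$id)
  molecules[[subset$id[ord[1]]]]
}

# run code with the caller's RNG state untouched
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
  invisible(NULL)
}
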