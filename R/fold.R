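#' Energy constants of the built-in folding model
#'
#' The built-in engine scores non-crossing secondary structures with a
#' simplified nearest-neighbour model (all values kcal/mol):
#' * per-pair strengths for the 6 canonical pairs (GC/CG -3.3, AU/UA -2.1,
#'   GU/UG -1.4); a stack of two adjacent pairs contributes the mean of the
#'   two strengths;
#' * hairpin loop of size s >= 3: `3.5 + 0.3 (s - 3)`;
#' * bulge of size b: `3.0 + 0.3 b`; internal loop of total size s:
#'   `2.5 + 0.3 s` (size capped at 30);
#' * multiloop: `3.4 + 0.4 per branch (closing pair included) + 0.1 per
#'   unpaired loop base`; exterior bases are free.
#'
#' These constants are deliberately simple and symmetric (a reverse
#' complemented Watson-Crick window folds to the mirrored structure); MFE
#' values are model-relative and only comparable within one backend.
#'
#' @return Named list of constants consumed by the folding backend.
#' @export
fold_energy_params <- function() {
  list(
    pair_strength = c(AU = -2.1, UA = -2.1, GC = -3.3, CG = -3.3,
                      GU = -1.4, UG = -1.4),
    hp_a = 3.5, hp_b = 0.3,
    bulge_a = 3.0, bulge_b = 0.3,
    int_a = 2.5, int_b = 0.3,
    ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
    max_loop = 30L, min_hairpin = 3L
  )
}

.encode_rna <- function(sequence) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  codes <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(ch %in% names(codes))) {
    stop("invalid base(s) in sequence: ",
         paste(unique(ch[!ch %in% names(codes)]), collapse = ","))
  }
  list(seq = s, codes = unname(codes[ch]))
}

#' Predict the minimum-free-energy secondary structure of an RNA window
#'
#' Runs the selected folding backend and returns the structure in dot-bracket
#' notation together with its free energy. The built-in backend is a
#' Zuker-style dynamic program over the energy model of
#' [fold_energy_params()]; any function mapping a sequence to
#' `list(dotbracket=, mfe=)` can be supplied instead (e.g. an external
#' RNAfold adapter), in which case MFE values follow that engine's model.
#'
#' @param sequence RNA (or DNA; `T` is read as `U`) string over `AUCGN`;
#'   `N` never pairs.
#' @param backend A backend function; default [fold_backend_builtin()].
#' @return Object of class `fold_prediction`: `sequence`, `dotbracket`,
#'   `mfe`.
#' @export
fold_mfe <- function(sequence, backend = fold_backend_builtin()) {
  enc <- .encode_rna(sequence)
  res <- backend(enc$seq)
  structure(list(sequence = enc$seq, dotbracket = res$dotbracket,
                 mfe = res$mfe),
            class = "fold_prediction")
}

#' @export
print.fold_prediction <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", format(round(x$mfe, 2)),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Built-in folding backend
#' @return A function `sequence -> list(dotbracket, mfe)` running the
#'   built-in dynamic program.
#' @export
fold_backend_builtin <- function() {
  par <- fold_energy_params()
  function(sequence) {
    codes <- .encode_rna(sequence)$codes
    res <- fold_seq_cpp(codes, par)
    list(dotbracket = res$dotbracket, mfe = res$mfe)
  }
}

#' RNAfold adapter backend
#'
#' Wraps a local ViennaRNA `RNAfold` executable as a folding backend, for
#' users wanting Turner-parameter energies. Structures and MFEs from this
#' backend are not comparable with built-in ones.
#'
#' @param exe Path to the RNAfold executable.
#' @return A backend function for [fold_mfe()].
#' @export
fold_backend_rnafold <- function(exe = "RNAfold") {
  force(exe)
  function(sequence) {
    out <- system2(exe, args = "--noPS", input = sequence, stdout = TRUE)
    line <- out[2]
    db <- sub(" .*$", "", line)
    mfe <- as.numeric(gsub("[() ]", "", sub("^[.()]+ ", "", line)))
    list(dotbracket = db, mfe = mfe)
  }
}

#' Fold the windows of an extracted-window table
#'
#' @param windows Tibble from [extract_window()] (column `window`).
#' @param backend Folding backend.
#' @return `windows` with `dotbracket` and `mfe` columns added.
#' @export
fold_windows <- function(windows, backend = fold_backend_builtin()) {
  preds <- purrr::map(windows$window, function(w) {
    f <- fold_mfe(w, backend = backend)
    list(db = f$dotbracket, mfe = f$mfe)
  })
  windows |>
    mutate(dotbracket = purrr::map_chr(preds, "db"),
           mfe = purrr::map_dbl(preds, "mfe"))
}

#' Loop membership of a position in a folded structure
#'
#' A position is "in a loop" iff it is unpaired. The loop type is derived
#' from the innermost enclosing pair: none -> `exterior`; 0 branches inside
#' -> `hairpin`; 1 branch -> `internal/bulge`; >= 2 branches -> `multiloop`.
#'
#' @param fold A `fold_prediction` (or plain dot-bracket string).
#' @param offset 1-based position within the structure.
#' @return List with `in_loop` (logical) and `loop_type` (character or
#'   `NA` for paired positions).
#' @export
is_loop <- function(fold, offset) {
  db <- if (inherits(fold, "fold_prediction")) fold$dotbracket else fold
  n <- nchar(db)
  if (offset < 1 || offset > n) stop("offset out of range")
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (ch[offset] != ".") return(list(in_loop = FALSE, loop_type = NA_character_))
  # pair table
  mate <- integer(n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      j <- stk[length(stk)]; stk <- stk[-length(stk)]
      mate[i] <- j; mate[j] <- i
    }
  }
  # innermost enclosing pair: walk left from offset tracking balance
  encl <- 0L
  bal <- 0L
  if (offset > 1) {
    for (i in (offset - 1):1) {
      if (ch[i] == ")") bal <- bal + 1L
      else if (ch[i] == "(") {
        if (bal == 0L) { encl <- i; break }
        bal <- bal - 1L
      }
    }
  }
  if (encl == 0L) return(list(in_loop = TRUE, loop_type = "exterior"))
  # count branches directly inside (encl, mate[encl])
  i <- encl + 1L
  jend <- mate[encl]
  branches <- 0L
  while (i < jend) {
    if (ch[i] == "(") {
      branches <- branches + 1L
      i <- mate[i] + 1L
    } else i <- i + 1L
  }
  type <- if (branches == 0L) "hairpin"
  else if (branches == 1L) "internal/bulge"
  else "multiloop"
  list(in_loop = TRUE, loop_type = type)
}
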