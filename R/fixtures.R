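fixture_registry <- function() {
  list(
    tm_p18599 = list(
      fasta = "tm_p18599.fasta",
      model = "tm_p18599_synthetic_model.txt",
      notes = paste(
        "Transmembrane-topology worked example: the first 100 residues of",
        "the 5-hydroxytryptamine receptor 2A (UniProtKB P18599), with a",
        "3-state model (Inside / Membrane / Outside). The model parameters",
        "are SYNTHETIC SURROGATES, not trained values: they were built from",
        "background amino-acid frequencies with a hydropathy-weighted",
        "Membrane emission row and satisfy the structural constraints of",
        "the problem (I<->O transitions are impossible, so both are 0;",
        "self-transitions of I and M are near 1)."))
  )
}

#' Bundled worked examples
#'
#' `list_fixtures()` names the examples shipped with the package;
#' `load_fixture()` loads one, ready to run through the forward, backward,
#' Viterbi and posterior-decoding algorithms.
#'
#' The `"tm_p18599"` fixture is a transmembrane-segment prediction
#' exercise: a 100-residue N-terminal fragment of the 5-hydroxytryptamine
#' receptor 2A bound to a 3-state model with hidden states I (inside,
#' cytosolic), M (membrane-embedded) and O (outside). Its parameters are
#' synthetic surrogates (see the bundle's `notes`): plausible values
#' satisfying the physical constraints of membrane topology, not trained
#' probabilities.
#'
#' @param name fixture name, e.g. `"tm_p18599"`.
#' @return `load_fixture()`: an object of class `hmm_fixture` with
#'   elements `name`, `sequence` (an [hmm_sequence()]), `model` (an
#'   [hmm_model()]), `sequence_id`, and `notes`. `list_fixtures()`: a
#'   character vector of names.
#' @examples
#' fx <- load_fixture("tm_p18599")
#' length(fx$sequence)  # 100
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  entry <- reg[[name]]
  fasta_path <- system.file("extdata", entry$fasta, package = "hmmtutor",
                            mustWork = TRUE)
  model_path <- system.file("extdata", entry$model, package = "hmmtutor",
                            mustWork = TRUE)
  model <- read_model(model_path)
  seqs <- read_fasta(fasta_path)
  structure(list(
    name = name,
    sequence = hmm_sequence(seqs[[1L]], model$alphabet),
    sequence_id = names(seqs)[1L],
    model = model,
    notes = entry$notes),
    class = "hmm_fixture")
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() names(fixture_registry())

#' @export
print.hmm_fixture <- function(x, ...) {
  cat(sprintf("<hmm_fixture> %s\n", x$name))
  print(x$sequence)
  print(x$model)
  cat(strwrap(x$notes, width = 76), sep = "\n")
  invisible(x)
}
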