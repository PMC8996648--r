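#' Specification for a synthetic MEDLINE-like corpus
#'
#' Describes a two-class corpus (relevant vs irrelevant records) in which
#' designated *signal* terms and MeSH headings occur with a higher
#' probability in relevant records, on top of a Zipf-distributed background
#' vocabulary of neutral pseudo-words. The defaults emulate the structure
#' of a prognostic-factor reference set: 73 relevant records inside a
#' baseline retrieval of around 1,500, with the filter's free-text terms
#' planted at rates that give near-complete coverage of the relevant class
#' and substantial leakage into the irrelevant class.
#'
#' @param n_relevant,n_irrelevant Class sizes.
#' @param signal_terms Data frame with `term`, `p_relevant`,
#'   `p_irrelevant`: per-record occurrence probabilities of each term in
#'   each class.
#' @param mesh_signal Data frame with `heading`, `p_relevant`,
#'   `p_irrelevant` for planted MeSH headings.
#' @param background_vocab_size Size of the neutral background vocabulary.
#' @param mean_abstract_length Mean abstract length in tokens (Poisson).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_relevant = 73,
                        n_irrelevant = 1400,
                        signal_terms = default_signal_terms(),
                        mesh_signal = default_mesh_signal(),
                        background_vocab_size = 500,
                        mean_abstract_length = 80,
                        seed = 1) {
  signal_terms <- tibble::as_tibble(signal_terms)
  mesh_signal <- tibble::as_tibble(mesh_signal)
  stopifnot(
    n_relevant >= 0, n_irrelevant >= 0,
    all(c("term", "p_relevant", "p_irrelevant") %in% names(signal_terms)),
    all(c("heading", "p_relevant", "p_irrelevant") %in% names(mesh_signal)),
    background_vocab_size >= 1, mean_abstract_length > 0
  )
  probs <- c(signal_terms$p_relevant, signal_terms$p_irrelevant,
             mesh_signal$p_relevant, mesh_signal$p_irrelevant)
  if (any(probs < 0 | probs > 1)) {
    stop("signal probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_relevant = as.integer(n_relevant),
    n_irrelevant = as.integer(n_irrelevant),
    signal_terms = signal_terms,
    mesh_signal = mesh_signal,
    background_vocab_size = as.integer(background_vocab_size),
    mean_abstract_length = mean_abstract_length,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

#' @rdname corpus_spec
#' @export
default_signal_terms <- function() {
  tibble::tribble(
    ~term,           ~p_relevant, ~p_irrelevant,
    "prognostic",    0.55,        0.15,
    "prognosis",     0.35,        0.10,
    "predicted",     0.30,        0.12,
    "risk",          0.50,        0.25,
    "cohort",        0.30,        0.08,
    "incidence",     0.20,        0.07,
    "survival",      0.30,        0.10,
    "course",        0.10,        0.05,
    "causal factor", 0.05,        0.01
  )
}

#' @rdname corpus_spec
#' @export
default_mesh_signal <- function() {
  tibble::tribble(
    ~heading,            ~p_relevant, ~p_irrelevant,
    "Risk Factors",      0.35,        0.15,
    "Cohort Studies",    0.25,        0.08,
    "Prognosis",         0.30,        0.05,
    "Incidence",         0.15,        0.05,
    "Survival Analysis", 0.20,        0.05,
    "Follow-Up Studies", 0.15,        0.08,
    "Mortality",         0.10,        0.05
  )
}

#' Generate a synthetic corpus with planted term statistics
#'
#' Deterministically (given `spec$seed`) draws `n_relevant + n_irrelevant`
#' records. Each record gets a title of background tokens, a
#' Poisson-length abstract of background tokens, neutral MeSH headings,
#' and then each signal term/heading independently with its class's
#' probability; planted terms are inserted as whole tokens at a random
#' position of title or abstract, so truncation and adjacency matching are
#' exercised naturally. Background tokens are drawn from a Zipf-like
#' (probability proportional to 1/rank) vocabulary whose head is ordinary
#' English function words — so that, as in real text, the tokens with the
#' highest document frequency are stopwords — and whose tail is
#' `background_vocab_size` neutral pseudo-words that cannot collide with
#' real search terms.
#'
#' @param spec A [corpus_spec()].
#' @return A list: `records` (tibble of all records, shuffled), and
#'   `reference` (a [reference_set()] of the relevant ids).
#' @examples
#' cs <- corpus_spec(n_relevant = 5, n_irrelevant = 10, seed = 42)
#' generate_corpus(cs)$reference
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n_total <- spec$n_relevant + spec$n_irrelevant
  if (n_total == 0) stop("zero records requested", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  # Zipf head = function words (as in real text, where the most frequent
  # tokens are stopwords the frequency analysis strips); tail = neutral
  # content pseudo-words that cannot collide with real search terms.
  vocab <- c(default_stopwords(),
             sprintf("vocab%04d", seq_len(spec$background_vocab_size)))
  zipf <- 1 / seq_along(vocab)
  zipf <- zipf / sum(zipf)
  neutral_mesh <- c("Humans", "Female", "Male", "Adult", "Middle Aged",
                    "Aged", "Treatment Outcome")

  draw_record <- function(i, relevant) {
    title_toks <- sample(vocab, 8, replace = TRUE, prob = zipf)
    abs_len <- max(5, rpois(1, spec$mean_abstract_length))
    abs_toks <- sample(vocab, abs_len, replace = TRUE, prob = zipf)
    p <- if (relevant) spec$signal_terms$p_relevant
         else spec$signal_terms$p_irrelevant
    present <- runif(nrow(spec$signal_terms)) < p
    for (tm in spec$signal_terms$term[present]) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (runif(1) < 0.3) {
        pos <- sample.int(length(title_toks) + 1, 1)
        title_toks <- append(title_toks, toks, after = pos - 1)
      } else {
        pos <- sample.int(length(abs_toks) + 1, 1)
        abs_toks <- append(abs_toks, toks, after = pos - 1)
      }
    }
    pm <- if (relevant) spec$mesh_signal$p_relevant
          else spec$mesh_signal$p_irrelevant
    mesh <- c(spec$mesh_signal$heading[runif(nrow(spec$mesh_signal)) < pm],
              sample(neutral_mesh, sample.int(3, 1)))
    tibble::tibble(
      id = sprintf(if (relevant) "2%06d" else "1%06d", i),
      title = paste(title_toks, collapse = " "),
      abstract = paste(abs_toks, collapse = " "),
      mesh = list(unique(mesh)),
      year = sample(1990:2022, 1)
    )
  }

  rel <- lapply(seq_len(spec$n_relevant), draw_record, relevant = TRUE)
  irr <- lapply(seq_len(spec$n_irrelevant), draw_record, relevant = FALSE)
  records <- dplyr::bind_rows(c(rel, irr))
  records <- records[sample.int(nrow(records)), ]
  records <- validate_records(records)
  if (spec$n_relevant > 0) {
    ref <- reference_set("synthetic", sprintf("2%06d", seq_len(spec$n_relevant)))
  } else {
    ref <- NULL
  }
  list(records = records, reference = ref)
}

#' Closed-form expected sensitivity/specificity of a term filter
#'
#' For a record class in which signal feature i occurs independently with
#' probability `p[i]`, the probability that an OR-filter over those
#' features retrieves a record is `1 - prod(1 - p)`. Expressed in percent.
#'
#' @param p Vector of per-feature occurrence probabilities.
#' @return Expected retrieval percentage.
#' @export
expected_retrieval_pct <- function(p) {
  100 * (1 - prod(1 - p))
}
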