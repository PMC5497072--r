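# End-to-end pipeline: extract -> tokenize -> featurize -> per-topic
# balanced cross-validation -> reports.

#' Tokenize and featurize a corpus of messages
#'
#' Extracts the question from each message, tokenizes it and extracts all
#' feature families. The background document-frequency table defaults to
#' the corpus itself.
#'
#' @param messages list of `chq_message`.
#' @param resources list with `dictionary`, `pos_dictionary`,
#'   `interrogatives`, `lexicon` (see [synth_resources()]).
#' @param background optional `chq_df_table`; computed from the corpus when
#'   `NULL`.
#' @param marker template marker for question extraction.
#' @return list with `questions`, `tokens`, `vectors`, `space`, `matrix`,
#'   `background`.
#' @export
featurize_corpus <- function(messages, resources = synth_resources(),
                             background = NULL, marker = DEFAULT_MARKER) {
  questions <- lapply(messages, extract_question, marker = marker)
  tokens <- lapply(questions, tokenize_question,
                   dictionary = resources$dictionary,
                   pos_dictionary = resources$pos_dictionary,
                   interrogatives = resources$interrogatives)
  if (is.null(background)) background <- generate_df_table(tokens)
  vectors <- lapply(tokens, extract_features,
                    lexicon = resources$lexicon, background = background)
  space <- build_feature_space(vectors)
  x <- feature_matrix(vectors, space)
  list(questions = questions, tokens = tokens, vectors = vectors,
       space = space, matrix = x, background = background)
}

#' Run the full classification pipeline on a labelled corpus
#'
#' For each of the six primary topics: build the one-vs-rest labels,
#' under-sample the majority class to balance, and run k-fold
#' cross-validation with per-fold Phi-score feature selection. Also fits a
#' per-topic Phi report on the whole balanced sample (the per-task feature
#' reduction view).
#'
#' @param corpus a `chq_synth_corpus`, or a list with `messages` (list of
#'   `chq_message`) and `gold` (list of character topic sets).
#' @param resources dictionary resources; see [featurize_corpus()].
#' @param k number of CV folds.
#' @param seed master seed; per-topic sampling and fold seeds derive from
#'   it.
#' @param classifier classifier family passed down to [train_binary()].
#' @param select perform Phi selection (default `TRUE`).
#' @param topics topics to evaluate (default all six).
#' @return a `chq_pipeline_result`: list with `report`
#'   (`chq_evaluation_report`), `cv` (per-topic `chq_cv_result`),
#'   `phi_reports` (per-topic whole-sample `chq_phi_report`), `features`
#'   (the [featurize_corpus()] output), `seed`.
#' @export
run_pipeline <- function(corpus, resources = synth_resources(), k = 10L,
                         seed = 1L, classifier = "svm", select = TRUE,
                         topics = PRIMARY_TOPICS) {
  stopifnot(!is.null(corpus$messages), !is.null(corpus$gold))
  feats <- featurize_corpus(corpus$messages, resources)
  x <- feats$matrix
  gold <- corpus$gold
  ids <- seq_len(nrow(x))

  cv_by_topic <- list()
  phi_reports <- list()
  for (i in seq_along(topics)) {
    tp <- topics[i]
    labels <- vapply(gold, function(g) tp %in% g, logical(1))
    if (sum(labels) < 2L || sum(!labels) < 2L) {
      chq_stop("topic ", tp, " has fewer than 2 instances in a class",
               class = "chqclass_invalid_input")
    }
    task_seed <- seed + i
    keep <- under_sample(ids, labels, seed = task_seed)
    xb <- x[keep, , drop = FALSE]
    yb <- labels[keep]
    cv_by_topic[[tp]] <- cross_validate(xb, yb, feats$space, k = k,
                                        seed = task_seed,
                                        classifier = classifier,
                                        select = select)
    phi_reports[[tp]] <- select_features(phi_scores(xb, yb),
                                         feats$space$type, feats$space$key)
  }
  structure(
    list(report = evaluation_report(cv_by_topic), cv = cv_by_topic,
         phi_reports = phi_reports, features = feats, seed = seed),
    class = "chq_pipeline_result"
  )
}

#' @export
print.chq_pipeline_result <- function(x, ...) {
  cat("<pipeline result> seed", x$seed, "-",
      nrow(x$features$space), "features\n")
  print(x$report)
  invisible(x)
}

#' Train final one-vs-rest models on full balanced samples
#'
#' Unlike [run_pipeline()] (which cross-validates), this fits one deployable
#' model per topic on the whole balanced sample, for use with
#' [predict_topics()].
#'
#' @inheritParams run_pipeline
#' @return named list of `chq_topic_model` plus attribute `features`.
#' @export
train_topic_models <- function(corpus, resources = synth_resources(),
                               seed = 1L, classifier = "svm", select = TRUE,
                               topics = PRIMARY_TOPICS) {
  feats <- featurize_corpus(corpus$messages, resources)
  x <- feats$matrix
  ids <- seq_len(nrow(x))
  models <- list()
  for (i in seq_along(topics)) {
    tp <- topics[i]
    labels <- vapply(corpus$gold, function(g) tp %in% g, logical(1))
    keep <- under_sample(ids, labels, seed = seed + i)
    models[[tp]] <- train_binary(tp, x[keep, , drop = FALSE], labels[keep],
                                 feats$space, classifier = classifier,
                                 select = select, seed = seed + i)
  }
  attr(models, "features") <- feats
  models
}

#' Load a pipeline configuration from YAML
#'
#' Fields: `dictionary`, `pos_dictionary`, `interrogatives`, `lexicon`,
#' `df_table` (paths; the first four default to the bundled fixtures),
#' `marker`, `folds`, `seed`, `classifier`, `select`. Referenced files must
#' exist.
#'
#' @param path YAML file.
#' @return list with `resources`, `background`, `marker`, `folds`, `seed`,
#'   `classifier`, `select`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bundled <- function(name) system.file("extdata", name, package = "chqclass")
  path_of <- function(field, default) {
    p <- cfg[[field]]
    if (is.null(p)) return(default)
    if (!file.exists(p)) {
      chq_stop("config file not found: ", field, " = ", p,
               class = "chqclass_invalid_input")
    }
    p
  }
  resources <- list(
    dictionary = load_dictionary(path_of("dictionary", bundled("segdict.tsv"))),
    pos_dictionary = load_pos_dictionary(
      path_of("pos_dictionary", bundled("posdict.tsv"))),
    interrogatives = load_dictionary(
      path_of("interrogatives", bundled("interrogatives.tsv"))),
    lexicon = load_lexicon(path_of("lexicon", bundled("lexicon.tsv")))
  )
  background <- if (!is.null(cfg$df_table)) {
    read_df_table(path_of("df_table", NULL))
  }
  list(resources = resources, background = background,
       marker = if (is.null(cfg$marker)) DEFAULT_MARKER else cfg$marker,
       folds = if (is.null(cfg$folds)) 10L else as.integer(cfg$folds),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       classifier = if (is.null(cfg$classifier)) "svm" else cfg$classifier,
       select = if (is.null(cfg$select)) TRUE else isTRUE(cfg$select))
}
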