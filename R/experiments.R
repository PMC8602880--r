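# Scripted reproductions of the simulation experiments: the standard
# queried-explanation runs, the confabulation run, the replay score and the
# answer-consistency predicate.

#' Run the standard three-epoch task
#'
#' Solve the maze, hear the query, answer it. The agent first seeks out the
#' cue, then the rewarded arm; after the query epoch it explains the queried
#' move in a seven-word answer sentence.
#'
#' @param query_type `"first"` or `"second"`: which move is queried.
#' @param true_context `"left"` or `"right"`: the rewarded arm.
#' @param seed Integer seed.
#' @param config Optional [task_config()] overriding the defaults (its
#'   `query_type`/`true_context`/`seed` are replaced by the arguments).
#' @param sever_bias Replace the descending policy bias by a uniform bias
#'   (negative control for replay).
#' @return List with `transcript` (a `"transcript"`), `record` (the
#'   `"hier_record"`), and `answer` (the named answer slots, when an answer
#'   epoch occurred).
#' @export
run_standard <- function(query_type = "second", true_context = "right",
                         seed = 1L, config = NULL, sever_bias = FALSE) {
  if (is.null(config)) config <- task_config()
  config$query_type <- match.arg(query_type, QUERIES)
  config$true_context <- match.arg(true_context, CONTEXTS)
  config$seed <- as.integer(seed)
  config$epochs <- c("solve", "query", "answer")
  hm <- build_model(config)
  rec <- run_hierarchy(hm, build_environment(config), seed = seed,
                       sever_bias = sever_bias)
  tx <- as_transcript(rec)
  ans <- answer_slots(tx, which(config$epochs == "answer")[1])
  list(transcript = tx, record = rec, answer = ans)
}

#' Run the confabulation variant
#'
#' The maze-solving epoch never happens: the agent starts at the query epoch
#' and is given two answer epochs to explain a course of action it never
#' pursued. The first answer is internally inconsistent; after hearing
#' itself, the agent revises it into a coherent (if confabulated) story.
#'
#' @param seed Integer seed.
#' @param query_type Which move is queried (default `"first"`).
#' @param config Optional [task_config()] (epochs are forced to
#'   query, answer, answer).
#' @return List with `transcript`, `record`, `answers` (slots per answer
#'   epoch) and `verdicts` (a [consistency_check()] result per answer).
#' @export
run_confabulation <- function(seed = 1L, query_type = "first",
                              config = NULL) {
  if (is.null(config)) config <- task_config()
  config$query_type <- match.arg(query_type, QUERIES)
  config$seed <- as.integer(seed)
  config$epochs <- c("query", "answer", "answer")
  hm <- build_model(config)
  rec <- run_hierarchy(hm, build_environment(config), seed = seed)
  tx <- as_transcript(rec)
  ans_idx <- which(config$epochs == "answer")
  answers <- lapply(ans_idx, function(e) answer_slots(tx, e))
  names(answers) <- paste0("answer", seq_along(answers))
  verdicts <- lapply(answers, consistency_check)
  list(transcript = tx, record = rec, answers = answers,
       verdicts = verdicts)
}

#' Extract a transcript from a hierarchical run
#'
#' @param record A `"hier_record"` from [run_hierarchy()].
#' @return A `"transcript"`: per epoch the heard and spoken token sequences,
#'   the maze action sequence, the maximum a posteriori location sequence
#'   and the context-posterior trace.
#' @export
as_transcript <- function(record) {
  m1 <- record$model$level1
  vocab <- m1$outcomes$heard
  eps <- lapply(record$epochs, function(er) {
    tr <- er$trial
    heard <- vocab[tr$observations["heard", ]]
    spoken <- vocab[tr$observations["spoken", ]]
    acts <- if (nrow(tr$actions) > 0)
      m1$actions$location[tr$actions[, "location"]] else character(0)
    map_loc <- vapply(tr$beliefs, function(b) {
      LOCATIONS[which_max_tie(b$location)]
    }, "")
    ctx <- vapply(tr$beliefs, function(b) b$context, numeric(2))
    rownames(ctx) <- CONTEXTS
    list(type = er$type, heard = heard, spoken = spoken,
         actions = acts, map_locations = map_loc,
         context_posterior = ctx)
  })
  structure(list(epochs = eps,
                 query_type = record$model$config$query_type,
                 true_context = record$model$config$true_context,
                 seed = record$model$config$seed),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript: ", length(x$epochs), " epochs | query ", x$query_type,
      " | context ", x$true_context, ">\n", sep = "")
  for (ep in x$epochs) {
    cat(sprintf("  [%s]\n", ep$type))
    if (any(ep$heard != "silence")) {
      cat("    heard: ", paste(ep$heard, collapse = " "), "\n", sep = "")
    }
    if (any(ep$spoken != "silence")) {
      cat("    spoken:", paste(ep$spoken, collapse = " "), "\n")
    }
    if (length(ep$actions)) {
      cat("    actions:", paste(ep$actions, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# Answer-frame slot tokens spoken during epoch `e` of a transcript:
# positions 2 (knowledge), 4 (side), 6 (verb), 7 (destination).
answer_slots <- function(transcript, e) {
  if (is.na(e) || e > length(transcript$epochs)) return(NULL)
  ep <- transcript$epochs[[e]]
  if (ep$type != "answer" || length(ep$spoken) < 7L) return(NULL)
  c(knowledge = ep$spoken[2], side = ep$spoken[4], verb = ep$spoken[6],
    destination = sub("^the-", "", ep$spoken[7]))
}

#' Check the internal consistency of an answer
#'
#' An answer (knowledge, side, verb, destination) is consistent when the
#' semantic rules of the narrative level — [semantic_link_table()] applied
#' to the asserted destination and the asserted reward side — reproduce the
#' asserted knowledge and verb. For example, claiming not to have known the
#' reward location while reporting a move straight to the rewarded arm is
#' inconsistent.
#'
#' @param answer Named character vector with elements `knowledge`, `side`,
#'   `verb`, `destination` (tokens as spoken; `"the-"` prefixes and
#'   `"-arm"` suffixes are tolerated).
#' @return List of class `"consistency_verdict"` with `consistent` (logical)
#'   and `realizable` (data frame of the (move destination, reward) tuples
#'   under which the answer is realizable; empty when inconsistent).
#' @export
consistency_check <- function(answer) {
  need <- c("knowledge", "side", "verb", "destination")
  if (is.null(answer) || !all(need %in% names(answer))) {
    stop("consistency_check: answer slots incomplete", call. = FALSE)
  }
  ans <- sub("^the-", "", answer)
  dest <- sub("-arm$", "", ans[["destination"]])
  if (!dest %in% LOCATIONS || !ans[["side"]] %in% CONTEXTS ||
      !ans[["knowledge"]] %in% KNOWLEDGE || !ans[["verb"]] %in% VERBS) {
    stop("consistency_check: unknown token in answer", call. = FALSE)
  }
  grid <- expand.grid(move = LOCATIONS, reward = CONTEXTS,
                      stringsAsFactors = FALSE)
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- semantic_link_table(grid$move[i], grid$reward[i])
    identical(unname(pred[["knowledge"]]), unname(ans[["knowledge"]])) &&
      identical(unname(pred[["verb"]]), unname(ans[["verb"]])) &&
      identical(sub("-arm$", "", pred[["destination"]]), dest) &&
      identical(grid$reward[i], unname(ans[["side"]]))
  }, TRUE)
  structure(list(consistent = any(ok), realizable = grid[ok, , drop = FALSE]),
            class = "consistency_verdict")
}

#' @export
print.consistency_verdict <- function(x, ...) {
  cat("<consistency_verdict: ",
      if (x$consistent) "consistent" else "inconsistent", ">\n", sep = "")
  if (nrow(x$realizable)) print(x$realizable)
  invisible(x)
}

#' Replay score of a hierarchical run
#'
#' Fraction of the first three time steps of every post-maze epoch at which
#' the maximum a posteriori location belief agrees with the corresponding
#' step of the maze-solving epoch. A score of 1 means the location beliefs
#' replay the solved trajectory exactly during the query and answer epochs.
#'
#' @param record A `"hier_record"` containing a `"solve"` epoch followed by
#'   at least one later epoch, each with at least three steps.
#' @return Numeric in `[0, 1]`.
#' @export
replay_score <- function(record) {
  types <- vapply(record$epochs, `[[`, "", "type")
  s <- which(types == "solve")[1]
  if (is.na(s) || s == length(types)) {
    stop("replay_score: need a solve epoch followed by later epochs",
         call. = FALSE)
  }
  map_loc <- function(er, t) which_max_tie(er$trial$beliefs[[t]]$location)
  for (er in record$epochs) {
    if (length(er$trial$beliefs) < 3L) {
      stop("replay_score: every epoch needs >= 3 steps", call. = FALSE)
    }
  }
  ref <- vapply(1:3, function(t) map_loc(record$epochs[[s]], t), 0L)
  later <- record$epochs[(s + 1):length(types)]
  hits <- unlist(lapply(later, function(er) {
    vapply(1:3, function(t) map_loc(er, t) == ref[t], TRUE)
  }))
  mean(hits)
}

#' Confidence in the narrative-level story
#'
#' The posterior probability of the maximum a posteriori level-2 tuple under
#' the factorised level-2 posterior at the end of an epoch (the product of
#' the per-factor maxima).
#'
#' @param epoch_record One element of a `"hier_record"`'s `epochs` list.
#' @return Numeric in `[0, 1]`.
#' @export
story_confidence <- function(epoch_record) {
  prod(vapply(epoch_record$level2_posterior, max, 0))
}

# Named MAP level of every level-2 factor at the end of an epoch.
map_level2 <- function(epoch_record, model) {
  q2 <- epoch_record$level2_posterior
  vapply(names(q2), function(f) {
    model$level2$factors[[f]][which_max_tie(q2[[f]])]
  }, "")
}
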