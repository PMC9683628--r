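# Session serialization. Interchange format is a tidy CSV with one row per
# trial; JSON mirrors it with nesting. Indices in files are 1-based (trial
# numbering as in the experiment); rules are encoded as "dim:feature" pairs
# joined by "|", choices as three symbols with "x" marking an unselected
# dimension.

.encode_rule <- function(rule) {
  d <- which(rule > 0L)
  paste(sprintf("%d:%d", d, rule[d]), collapse = "|")
}

.decode_rule <- function(s) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  rule <- integer(3)
  for (p in parts) {
    kv <- as.integer(strsplit(p, ":", fixed = TRUE)[[1]])
    if (length(kv) != 2L || anyNA(kv) || !(kv[1] %in% 1:3) ||
        !(kv[2] %in% 1:3)) {
      stop("malformed rule encoding: ", s, call. = FALSE)
    }
    rule[kv[1]] <- kv[2]
  }
  if (sum(rule > 0L) == 0L) stop("empty rule: ", s, call. = FALSE)
  rule
}

.encode_choice <- function(choice) {
  paste(ifelse(choice == 0L, "x", as.character(choice)), collapse = "")
}

.decode_choice <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) != 3L || !all(ch %in% c("x", "1", "2", "3"))) {
    stop("malformed choice encoding: ", s, call. = FALSE)
  }
  out <- integer(3L)
  out[ch != "x"] <- as.integer(ch[ch != "x"])
  out
}

.decode_stimulus <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) != 3L || !all(ch %in% c("1", "2", "3"))) {
    stop("malformed stimulus encoding: ", s, call. = FALSE)
  }
  as.integer(ch)
}

.session_columns <- c("session_id", "game_index", "complexity", "knowledge",
                      "true_rule", "trial_index", "choice", "stimulus",
                      "reward")

#' Flatten sessions to a tidy one-row-per-trial data.frame
#'
#' @param sessions A session or list of sessions.
#' @return Data.frame in the interchange schema (columns `session_id`,
#'   `game_index`, `complexity`, `knowledge`, `true_rule`, `trial_index`,
#'   `choice`, `stimulus`, `reward`; all indices 1-based).
#' @export
sessions_to_table <- function(sessions) {
  if (inherits(sessions, "session")) sessions <- list(sessions)
  rows <- list()
  for (s in sessions) {
    for (gi in seq_along(s$games)) {
      g <- s$games[[gi]]
      T_ <- length(g$rewards)
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = as.character(s$id),
        game_index = gi,
        complexity = g$spec$complexity,
        knowledge = if (g$spec$known) "known" else "unknown",
        true_rule = .encode_rule(g$spec$true_rule),
        trial_index = seq_len(T_),
        choice = vapply(seq_len(T_),
                        function(t) .encode_choice(g$choices[t, ]),
                        character(1)),
        stimulus = vapply(seq_len(T_),
                          function(t) paste(g$stimuli[t, ], collapse = ""),
                          character(1)),
        reward = g$rewards)
    }
  }
  do.call(rbind, rows)
}

#' Rebuild sessions from a tidy trial table
#'
#' Validates the schema and the task invariants (stimulus consistent with
#' choice, rule dimensionality equal to complexity); malformed rows are
#' reported with their row numbers.
#'
#' @param tab Data.frame in the schema of [sessions_to_table()].
#' @return List of sessions.
#' @export
table_to_sessions <- function(tab) {
  missing <- setdiff(.session_columns, names(tab))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) return(list())
  sessions <- list()
  for (sid in unique(tab$session_id)) {
    st <- tab[tab$session_id == sid, ]
    games <- list()
    for (gi in sort(unique(st$game_index))) {
      gt <- st[st$game_index == gi, ]
      gt <- gt[order(gt$trial_index), ]
      rows <- as.integer(rownames(gt))
      parse_row <- function(t, fn, field) {
        tryCatch(fn(gt[[field]][t]),
                 error = function(e) {
                   stop(sprintf("row %d: %s", rows[t], conditionMessage(e)),
                        call. = FALSE)
                 })
      }
      T_ <- nrow(gt)
      choices <- t(vapply(seq_len(T_),
                          function(t) parse_row(t, .decode_choice, "choice"),
                          integer(3)))
      stims <- t(vapply(seq_len(T_),
                        function(t) parse_row(t, .decode_stimulus,
                                              "stimulus"),
                        integer(3)))
      rule <- parse_row(1L, .decode_rule, "true_rule")
      if (!all(gt$reward %in% 0:1)) {
        bad <- rows[!(gt$reward %in% 0:1)]
        stop("out-of-range reward at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      known <- gt$knowledge[1] == "known"
      if (!all(gt$knowledge %in% c("known", "unknown"))) {
        stop("invalid knowledge flag in game ", gi, " of session ", sid,
             call. = FALSE)
      }
      spec <- game_spec(gt$complexity[1], known, true_rule = rule,
                        n_trials = T_)
      bad <- which(rowSums((choices > 0L) & (stims != choices)) > 0L)
      if (length(bad) > 0) {
        stop("stimulus contradicts choice at row(s) ",
             paste(rows[bad], collapse = ", "), call. = FALSE)
      }
      games[[length(games) + 1L]] <- new_game(spec, choices, stims,
                                              gt$reward)
    }
    sessions[[length(sessions) + 1L]] <- new_session(sid, games)
  }
  sessions
}

#' Write sessions to CSV
#'
#' @param sessions A session or list of sessions.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  write.csv(sessions_to_table(sessions), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read sessions from CSV
#'
#' @param path A CSV file in the interchange schema.
#' @return List of sessions.
#' @export
read_sessions_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(session_id = "character",
                                 true_rule = "character",
                                 choice = "character",
                                 stimulus = "character"))
  table_to_sessions(tab)
}

#' Write sessions to JSON
#'
#' Nested mirror of the CSV schema: one object per session with its games
#' and trial records.
#'
#' @param sessions A session or list of sessions.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sessions_json <- function(sessions, path) {
  if (inherits(sessions, "session")) sessions <- list(sessions)
  obj <- lapply(sessions, function(s) {
    list(session_id = as.character(s$id),
         games = lapply(s$games, function(g) {
           list(complexity = g$spec$complexity,
                knowledge = if (g$spec$known) "known" else "unknown",
                true_rule = .encode_rule(g$spec$true_rule),
                choice = apply(g$choices, 1, .encode_choice),
                stimulus = apply(g$stimuli, 1, paste, collapse = ""),
                reward = g$rewards)
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read sessions from JSON
#'
#' @param path A JSON file written by [write_sessions_json()].
#' @return List of sessions.
#' @export
read_sessions_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(obj, function(s) {
    games <- lapply(s$games, function(g) {
      T_ <- length(g$reward)
      choices <- t(vapply(g$choice, .decode_choice, integer(3)))
      stims <- t(vapply(g$stimulus, .decode_stimulus, integer(3)))
      spec <- game_spec(g$complexity, g$knowledge == "known",
                        true_rule = .decode_rule(g$true_rule),
                        n_trials = T_)
      new_game(spec, choices, stims, as.integer(g$reward))
    })
    new_session(s$session_id, games)
  })
}
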