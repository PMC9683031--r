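# Cascaded pattern-rule transducer over annotation sequences.  Rules are
# declared in a YAML dialect: sequence patterns over annotations with feature
# predicates and quantifiers, plus create/remove actions.  Phase control
# follows the appelt / first / all convention: appelt takes the longest match
# (ties broken by priority, then declaration order) and consumes it.

.quantifiers <- c("one", "optional", "star", "plus")

parse_quantifier <- function(q, where) {
  if (is.null(q)) return(c(1L, 1L))
  if (is.character(q) && length(q) == 1) {
    switch(q,
      one = c(1L, 1L),
      optional = c(0L, 1L),
      star = c(0L, .Machine$integer.max),
      plus = c(1L, .Machine$integer.max),
      abort(paste0(where, ": unknown quantifier '", q, "'"))
    )
  } else if (is.list(q) && !is.null(q$min) && !is.null(q$max)) {
    mn <- as.integer(q$min)
    mx <- as.integer(q$max)
    if (is.na(mn) || is.na(mx) || mn < 0 || mn > mx) {
      abort(paste0(where, ": invalid quantifier range (need 0 <= min <= max)"))
    }
    c(mn, mx)
  } else {
    abort(paste0(where, ": malformed quantifier"))
  }
}

parse_element <- function(el, where) {
  if (is.null(el$category)) abort(paste0(where, ": pattern element lacks a category"))
  qr <- parse_quantifier(el$quantifier, where)
  list(
    category = as.character(el$category),
    features = el$features %||% list(),
    in_ = lapply(el[["in"]] %||% list(), function(v) as.character(unlist(v))),
    regex = el$regex,
    min = qr[1], max = qr[2],
    bind = el$bind
  )
}

parse_action <- function(a, bound, where) {
  if (!is.null(a$create)) {
    cr <- a$create
    if (is.null(cr$category)) abort(paste0(where, ": create action lacks a category"))
    span <- cr$span %||% "match"
    if (!identical(span, "match") && !span %in% bound) {
      abort(paste0(where, ": create action references unbound label '", span, "'"))
    }
    feats <- lapply(cr$features %||% list(), function(v) {
      if (is.list(v) && !is.null(v$from)) {
        if (!identical(v$from, "match") && !v$from %in% bound) {
          abort(paste0(where, ": feature copy references unbound label '", v$from, "'"))
        }
        list(from = v$from, raw = isTRUE(v$raw), feature = v$feature)
      } else {
        v
      }
    })
    list(type = "create", category = as.character(cr$category),
         span = span, features = feats)
  } else if (!is.null(a$remove)) {
    lab <- if (is.list(a$remove)) a$remove$binding else a$remove
    if (!lab %in% bound) {
      abort(paste0(where, ": remove action references unbound label '", lab, "'"))
    }
    list(type = "remove", binding = as.character(lab))
  } else {
    abort(paste0(where, ": action must be create or remove"))
  }
}

parse_rule <- function(r, file) {
  where <- paste0(file, ", rule '", r$name %||% "?", "'")
  if (is.null(r$name)) abort(paste0(file, ": rule lacks a name"))
  if (is.null(r$pattern) || length(r$pattern) == 0) {
    abort(paste0(where, ": rule lacks a pattern"))
  }
  pattern <- lapply(r$pattern, parse_element, where = where)
  bound <- compact(map(pattern, "bind"))
  bound <- as.character(unlist(bound))
  if (anyDuplicated(bound)) abort(paste0(where, ": duplicate binding labels"))
  actions <- lapply(r$actions %||% list(), parse_action, bound = bound, where = where)
  if (length(actions) == 0) abort(paste0(where, ": rule has no actions"))
  list(
    name = as.character(r$name),
    priority = as.integer(r$priority %||% 0L),
    pattern = pattern, actions = actions
  )
}

#' Read one rule phase from a YAML file
#'
#' A phase file holds `phase: {name, control, input}` and `rules:` — an
#' ordered list of `{name, priority, pattern, actions}`.  All structural
#' problems (unknown quantifiers, actions referencing unbound labels,
#' duplicate rule names) are rejected at load time with the file and rule
#' named in the error.
#'
#' @param path YAML phase file.
#' @return A `bcc_phase` object.
#' @export
read_rule_phase <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$phase) || is.null(y$phase$name)) {
    abort(paste0(path, ": missing phase header"))
  }
  control <- y$phase$control %||% "appelt"
  if (!control %in% c("appelt", "first", "all")) {
    abort(paste0(path, ": unknown control style '", control, "'"))
  }
  input <- as.character(unlist(y$phase$input %||% list("Lookup")))
  rules <- lapply(y$rules %||% list(), parse_rule, file = basename(path))
  if (anyDuplicated(map_chr(rules, "name"))) {
    abort(paste0(path, ": duplicate rule names within the phase"))
  }
  structure(
    list(name = y$phase$name, control = control, input = input,
         rules = rules, file = basename(path)),
    class = "bcc_phase"
  )
}

#' Read an ordered rule cascade
#'
#' `paths` may be a directory (phase files are taken in lexical order — the
#' shipped cascade numbers its files) or an explicit ordered vector of YAML
#' files.  A phase whose input includes a category produced only by a later
#' phase is rejected at load time (a forward dependency would make the
#' cascade order inconsistent).
#'
#' @param paths Directory or character vector of phase file paths.
#' @return List of `bcc_phase` objects, in application order.
#' @export
read_cascade <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.ya?ml$", full.names = TRUE))
  }
  if (length(paths) == 0) abort("no phase files found")
  phases <- lapply(paths, read_rule_phase)
  produced_at <- list()
  for (i in seq_along(phases)) {
    for (r in phases[[i]]$rules) {
      for (a in r$actions) {
        if (a$type == "create" && is.null(produced_at[[a$category]])) {
          produced_at[[a$category]] <- i
        }
      }
    }
  }
  for (i in seq_along(phases)) {
    for (cat in phases[[i]]$input) {
      p <- produced_at[[cat]]
      if (!is.null(p) && p > i) {
        abort(paste0(
          "cascade ordering error: phase '", phases[[i]]$name,
          "' consumes '", cat, "', first produced by later phase '",
          phases[[p]]$name, "'"
        ))
      }
    }
  }
  phases
}

# ---- matching ---------------------------------------------------------------

elem_matches <- function(elem, ann_row, text) {
  if (ann_row$category != elem$category) return(FALSE)
  feats <- ann_row$features[[1]]
  for (nm in names(elem$features)) {
    v <- feats[[nm]]
    if (is.null(v) || !identical(as.character(v), as.character(elem$features[[nm]]))) {
      return(FALSE)
    }
  }
  for (nm in names(elem$in_)) {
    v <- feats[[nm]]
    if (is.null(v) || !as.character(v) %in% elem$in_[[nm]]) return(FALSE)
  }
  if (!is.null(elem$regex)) {
    covered <- substring(text, ann_row$start + 1L, ann_row$end)
    if (!grepl(elem$regex, covered, perl = TRUE)) return(FALSE)
  }
  TRUE
}

# Greedy, backtracking sequence match of `rule` over `anns` (sorted input
# annotations) starting exactly at character offset `at`.  Returns NULL or
# list(start, end, bindings = label -> integer row indices).
match_rule_at <- function(rule, anns, text, at) {
  starts <- anns$start
  next_rows <- function(pos, must_start = NULL) {
    cand <- which(starts >= pos)
    if (length(cand) == 0) return(integer())
    s <- min(starts[cand])
    if (!is.null(must_start) && s != must_start) return(integer())
    cand[starts[cand] == s]
  }
  n_elem <- length(rule$pattern)
  recur <- function(idx, pos, reps, bindings, consumed_any, first_elem_open) {
    if (idx > n_elem) {
      if (!consumed_any) return(NULL)
      return(list(end = pos, bindings = bindings))
    }
    elem <- rule$pattern[[idx]]
    # try consuming one more repeat (greedy) ...
    if (reps < elem$max) {
      rows <- next_rows(pos, must_start = if (first_elem_open) at else NULL)
      if (length(rows) > 0) {
        ord <- rows[order(-anns$end[rows])] # longer annotation first
        for (rw in ord) {
          if (!elem_matches(elem, anns[rw, ], text)) next
          b2 <- bindings
          if (!is.null(elem$bind)) b2[[elem$bind]] <- c(b2[[elem$bind]], rw)
          res <- recur(idx, anns$end[rw], reps + 1L, b2, TRUE, FALSE)
          if (!is.null(res)) return(res)
        }
      }
    }
    # ... then settle for what we have and advance to the next element
    if (reps >= elem$min) {
      return(recur(idx + 1L, pos, 0L, bindings,
                   consumed_any, first_elem_open && elem$min == 0L))
    }
    NULL
  }
  res <- recur(1L, at, 0L, list(), FALSE, TRUE)
  if (is.null(res)) return(NULL)
  list(start = at, end = res$end, bindings = res$bindings)
}

#' Find the best rule match at a position
#'
#' Under `appelt` control the winning match is (1) the longest in span,
#' tie-broken by (2) highest rule priority, then (3) earliest rule in file
#' order.  Under `first` the first declared rule that matches wins.  Under
#' `all`, every rule's match at the position is returned (as a list).
#'
#' @param phase A `bcc_phase`.
#' @param anns Input annotation table (already restricted to the phase's
#'   input categories and sorted).
#' @param text Document text.
#' @param at Character offset at which the match must start.
#' @return A match (list with `rule`, `start`, `end`, `bindings`), a list of
#'   matches under `all`, or `NULL`.
#' @export
match_at <- function(phase, anns, text, at) {
  matches <- list()
  for (ri in seq_along(phase$rules)) {
    rule <- phase$rules[[ri]]
    m <- match_rule_at(rule, anns, text, at)
    if (!is.null(m)) {
      m$rule <- rule
      m$rule_index <- ri
      if (phase$control == "first") return(m)
      matches[[length(matches) + 1L]] <- m
    }
  }
  if (length(matches) == 0) return(NULL)
  if (phase$control == "all") return(matches)
  ends <- map_int(matches, function(m) as.integer(m$end))
  prio <- map_int(matches, function(m) m$rule$priority)
  ord <- order(-ends, -prio, map_int(matches, "rule_index"))
  matches[[ord[1]]]
}

apply_actions <- function(match, text, next_id) {
  created <- list()
  removed <- integer()
  binding_span <- function(lab) {
    rows <- match$bindings[[lab]]
    c(min(match$anns_start[rows]), max(match$anns_end[rows]))
  }
  for (a in match$rule$actions) {
    if (a$type == "create") {
      sp <- if (identical(a$span, "match")) {
        c(match$start, match$end)
      } else {
        binding_span(a$span)
      }
      feats <- list()
      for (nm in names(a$features)) {
        v <- a$features[[nm]]
        if (is.list(v) && !is.null(v$from)) {
          if (!is.null(v$feature)) {
            # copy a feature value from the first annotation bound to the label
            rows <- match$bindings[[v$from]]
            feats[[nm]] <- match$anns_features[[rows[1]]][[v$feature]]
          } else {
            bsp <- if (identical(v$from, "match")) {
              c(match$start, match$end)
            } else {
              binding_span(v$from)
            }
            txt <- substring(text, bsp[1] + 1L, bsp[2])
            if (!v$raw) txt <- tolower(trimws(gsub("[[:space:]]+", " ", txt)))
            feats[[nm]] <- txt
          }
        } else {
          feats[[nm]] <- v
        }
      }
      created[[length(created) + 1L]] <- list(
        id = next_id, category = a$category,
        start = sp[1], end = sp[2], features = feats
      )
      next_id <- next_id + 1L
    } else {
      rows <- match$bindings[[a$binding]]
      removed <- c(removed, match$anns_id[rows])
    }
  }
  list(created = created, removed = removed, next_id = next_id)
}

#' Run one rule phase over a document's annotations
#'
#' The scanner advances left to right over the start offsets occupied by the
#' phase's input annotations.  After an `appelt` or `first` match consumes a
#' region, scanning resumes at the match end, so consumed matches never
#' overlap.  `create` actions add annotations (visible to later phases, not
#' to this one); `remove` actions delete the bound annotations.
#'
#' @param phase A `bcc_phase`.
#' @param text Document text.
#' @param anns Working annotation table (all categories).
#' @return The updated annotation table.
#' @export
run_phase <- function(phase, text, anns) {
  input <- ann_select(anns, category = phase$input)
  next_id <- if (nrow(anns) == 0) 1L else max(anns$id) + 1L
  created <- list()
  removed <- integer()
  offsets <- sort(unique(input$start))
  pos <- 0L
  for (off in offsets) {
    if (off < pos) next
    m <- match_at(phase, input, text, off)
    if (is.null(m)) next
    ms <- if (phase$control == "all") m else list(m)
    for (mm in ms) {
      mm$anns_start <- input$start
      mm$anns_end <- input$end
      mm$anns_id <- input$id
      mm$anns_features <- input$features
      res <- apply_actions(mm, text, next_id)
      created <- c(created, res$created)
      removed <- c(removed, res$removed)
      next_id <- res$next_id
    }
    if (phase$control != "all") pos <- ms[[1]]$end
  }
  out <- anns[!anns$id %in% removed, , drop = FALSE]
  if (length(created) > 0) {
    new <- annotation_tbl(
      category = map_chr(created, "category"),
      start = map_int(created, function(x) as.integer(x$start)),
      end = map_int(created, function(x) as.integer(x$end)),
      features = map(created, "features"),
      id = map_int(created, function(x) as.integer(x$id))
    )
    out <- bind_rows(out, new)
  }
  validate_annotations(out)
}

#' Run an ordered cascade of phases
#'
#' Phases are applied sequentially; each sees every annotation produced by
#' earlier phases.  Output is deterministic for a fixed document and rule
#' files: an empty phase list returns the document unchanged.
#'
#' @param phases List of `bcc_phase` objects from [read_cascade()].
#' @inheritParams run_phase
#' @return The updated annotation table.
#' @export
run_cascade <- function(phases, text, anns) {
  for (ph in phases) anns <- run_phase(ph, text, anns)
  anns
}
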