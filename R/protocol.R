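# Clinical line protocol for scoring visual acuity from per-optotype
# recognition outcomes: five letters per line, descend by 0.1 logMAR while
# at least one letter on the line is recognized, stop at a fully-failed
# line (or the floor), then score letter-by-letter.

#' Determine VA by the clinical line procedure
#'
#' Presents `letters_per_line` letters per line starting at `start` logMAR.
#' If at least one is recognized the level decreases by `step`; the trial
#' stops when a line yields no recognitions or after the floor line. The
#' final VA is the last attempted line's logMAR plus 0.02 per error
#' accumulated over all attempted lines (letter-by-letter scoring; a clean
#' run that fails an entire line therefore scores exactly the previous
#' line's value). Set `errors_last_line_only = TRUE` for the alternative
#' scoring that counts only the terminal line's errors.
#'
#' @param recognize Callback `function(letter, logmar)` returning a logical
#'   recognition flag.
#' @param start First (largest) level, logMAR.
#' @param floor_level Smallest level presented, logMAR.
#' @param step Line step, logMAR.
#' @param letters_per_line Letters per line (default 5).
#' @param per_letter_penalty logMAR per error (default 0.02).
#' @param errors_last_line_only Alternative scoring flag.
#' @param seed Seed for the letter draws.
#' @return Object of class `va_trial`: `final_va`, `total_errors`, and a
#'   per-line `lines` data frame (logmar, letters, flags).
#' @export
determine_va <- function(recognize, start = 1.0, floor_level = -0.3,
                         step = 0.1, letters_per_line = 5,
                         per_letter_penalty = 0.02,
                         errors_last_line_only = FALSE, seed = NULL) {
  if (start <= floor_level) stop("start must exceed the floor")
  if (step <= 0) stop("step must be positive")
  if (!is.null(seed)) set.seed(seed)
  levels <- round(seq(start, floor_level, by = -step), 2)
  lines <- list()
  total_errors <- 0L
  last_level <- NA_real_
  last_line_errors <- 0L
  for (lv in levels) {
    letters <- sample(sloan_letters, letters_per_line,
                      replace = letters_per_line > length(sloan_letters))
    flags <- vapply(letters, function(L) isTRUE(recognize(L, lv)), logical(1))
    errs <- sum(!flags)
    total_errors <- total_errors + errs
    last_line_errors <- errs
    last_level <- lv
    lines[[length(lines) + 1]] <- data.frame(
      logmar = lv, letters = paste(letters, collapse = ""),
      n_recognized = sum(flags), n_errors = errs)
    if (errs == letters_per_line) break  # fully failed line terminates
  }
  counted <- if (errors_last_line_only) last_line_errors else total_errors
  structure(list(final_va = round(last_level + per_letter_penalty * counted, 4),
                 total_errors = as.integer(total_errors),
                 last_level = last_level,
                 lines = do.call(rbind, lines),
                 scoring = if (errors_last_line_only) "last-line" else "all-lines"),
            class = "va_trial")
}

#' @export
print.va_trial <- function(x, ...) {
  cat(sprintf("<va_trial> final VA %.2f logMAR (%d errors over %d lines, %s scoring)\n",
              x$final_va, x$total_errors, nrow(x$lines), x$scoring))
  invisible(x)
}

#' Simulate the full VA measurement of one eye
#'
#' Binds [determine_va()]'s callback to the image pipeline plus a
#' recognizer. The recognizer may be a trained [train_recognizer()] model
#' (images are simulated per presentation), the string `"correlation"`
#' (template-correlation observer with per-level noise-free templates), or
#' any `function(letter, logmar)` (e.g. a psychometric observer), in which
#' case no images are simulated.
#'
#' @param zset The eye's [zernike_set()].
#' @param age Age, years.
#' @param recognizer See details.
#' @param config A [sim_config()].
#' @param seed Seed for letter draws and noise.
#' @param ... Passed to [determine_va()].
#' @return A `va_trial`.
#' @export
simulate_protocol <- function(zset, age, recognizer, config = sim_config(),
                              seed = 1, ...) {
  if (is.function(recognizer)) {
    return(determine_va(recognizer, seed = seed, ...))
  }
  grid <- pupil_grid(config$pupil_n, config$pad_factor, config$ppd)
  psf <- psf_from_pupil(pupil_function(zset, grid, config$rho_sc))
  if (identical(recognizer, "correlation")) {
    template_cache <- new.env(parent = emptyenv())
    cb <- function(letter, logmar) {
      key <- sprintf("%.2f", logmar)
      if (is.null(template_cache[[key]]))
        template_cache[[key]] <- letter_templates(logmar, config, zset, age)
      img <- simulate_optotype(zset, age, letter, logmar, config, psf = psf)
      correlation_recognizer(img, letter, template_cache[[key]])$recognized
    }
  } else if (inherits(recognizer, "cnn_recognizer")) {
    cb <- function(letter, logmar) {
      img <- simulate_optotype(zset, age, letter, logmar, config, psf = psf)
      classify(recognizer, img)$recognized
    }
  } else stop("recognizer must be a function, 'correlation', or a cnn_recognizer")
  determine_va(cb, seed = seed, ...)
}
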