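# Stage label codes and hypnogram token dialect.

#' Sleep stage levels
#'
#' The five AASM stages in fixed code order. Integer codes are
#' W = 0, N1 = 1, N2 = 2, N3 = 3, REM = 4 throughout the package.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Convert between stage names and integer codes
#'
#' @param stage Character vector of stage names among
#'   `stage_levels()`.
#' @param code Integer vector of codes in 0..4.
#' @return `stage_code()` returns integer codes (W = 0 ... REM = 4);
#'   `stage_name()` returns the corresponding names.
#' @examples
#' stage_code(c("W", "N3"))   # 0 3
#' stage_name(c(4L, 0L))      # "REM" "W"
#' @export
stage_code <- function(stage) {
  idx <- match(stage, stage_levels())
  if (anyNA(idx)) {
    stop("unknown stage name(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' @rdname stage_code
#' @export
stage_name <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 0L | code > 4L)) {
    stop("stage codes must be integers in 0..4")
  }
  stage_levels()[code + 1L]
}

# Sleep-EDF annotation dialect. "Sleep stage 3" and "Sleep stage 4"
# both merge into N3 (AASM). Movement/unscored epochs carry no valid
# stage and are marked DROP so they can be removed upstream.
.stage_token_map <- c(
  "Sleep stage W" = "W",
  "Sleep stage 1" = "N1",
  "Sleep stage 2" = "N2",
  "Sleep stage 3" = "N3",
  "Sleep stage 4" = "N3",
  "Sleep stage R" = "REM",
  "Movement time" = "DROP",
  "Sleep stage ?" = "DROP",
  # bare tokens, accepted in CSV hypnograms
  "W" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3",
  "R" = "REM", "N1" = "N1", "N2" = "N2", "N3" = "N3", "REM" = "REM",
  "M" = "DROP", "?" = "DROP"
)

#' Map a hypnogram token to a stage name or DROP
#'
#' Understands the Sleep-EDF annotation dialect (`"Sleep stage W"`,
#' `"Sleep stage 1"`, ..., `"Sleep stage R"`) and bare tokens
#' (`"W"`, `"1"`, ..., `"R"`, `"N1"`, ...). Stages 3 and 4 merge into
#' N3 per the AASM standard; movement and unscored tokens map to
#' `"DROP"`, meaning the epoch carries no usable label.
#'
#' @param token Character vector of raw hypnogram tokens.
#' @return Character vector over `c(stage_levels(), "DROP")`.
#' @export
stage_from_token <- function(token) {
  out <- unname(.stage_token_map[token])
  if (anyNA(out)) {
    stop("unknown hypnogram token(s): ",
         paste(unique(token[is.na(out)]), collapse = ", "))
  }
  out
}

#' All hypnogram tokens the dialect mapping accepts
#'
#' @return Character vector of every token `stage_from_token()` maps.
#' @export
stage_tokens <- function() names(.stage_token_map)

# canonical token written into generated hypnograms (Sleep-EDF dialect)
.stage_to_token <- c(W = "Sleep stage W", N1 = "Sleep stage 1",
                     N2 = "Sleep stage 2", N3 = "Sleep stage 3",
                     REM = "Sleep stage R")

stage_to_token <- function(stage) unname(.stage_to_token[stage])
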