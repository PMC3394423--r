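# box index of an objective vector on the additive epsilon grid; kept as
# numeric floors because f / epsilon can exceed integer range
.boxIndex <- function(f, epsilon) floor(f / epsilon)

#' Offer a candidate to the epsilon-dominance archive
#'
#' Box-based update on the additive grid \code{floor(f / epsilon)}:
#' \enumerate{
#'   \item reject the candidate if any member's box dominates its box, or any
#'     member's objective vector dominates its vector;
#'   \item if a member occupies the same box, keep whichever vector is closer
#'     (Euclidean) to the box's lower corner, incumbent winning ties;
#'   \item otherwise insert, deleting every member whose box or vector the
#'     candidate dominates.
#' }
#' The archive therefore always holds mutually non-dominated members, at
#' most one per box, and every rejected candidate is additively
#' epsilon-dominated by some member.
#'
#' @param archive an [EpsArchive-class].
#' @param objectives finite numeric vector (dimension = length(epsilon)).
#' @param position optional logical membership vector stored with the member.
#' @return The updated archive. Non-finite candidates are rejected with a
#'   warning.
#' @export
archiveInsert <- function(archive, objectives, position = NULL) {
  objectives <- as.numeric(objectives)
  if (length(objectives) != length(archive@epsilon))
    stop("objective dimension does not match the archive's epsilon")
  if (any(!is.finite(objectives))) {
    warning("rejecting candidate with non-finite objectives")
    return(archive)
  }
  eps <- archive@epsilon
  box <- .boxIndex(objectives, eps)
  k <- nrow(archive@objectives)
  if (k > 0L) {
    B <- archive@boxes
    Fm <- archive@objectives
    p <- length(eps)
    boxM <- matrix(box, k, p, byrow = TRUE)
    objM <- matrix(objectives, k, p, byrow = TRUE)
    # member box/vector dominates the candidate?
    if (any((rowSums(B <= boxM) == p & rowSums(B < boxM) > 0L) |
            (rowSums(Fm <= objM) == p & rowSums(Fm < objM) > 0L)))
      return(archive)
    same <- which(rowSums(B == boxM) == p)
    if (length(same)) {
      corner <- box * eps
      dNew <- sum((objectives - corner)^2)
      dOld <- sum((Fm[same, ] - corner)^2)
      if (dNew >= dOld) return(archive)      # incumbent wins ties
      keep <- rep(TRUE, k); keep[same] <- FALSE
    } else {
      # drop members whose box or vector the candidate dominates
      keep <- !((rowSums(boxM <= B) == p & rowSums(boxM < B) > 0L) |
                  (rowSums(objM <= Fm) == p & rowSums(objM < Fm) > 0L))
    }
    archive@objectives <- Fm[keep, , drop = FALSE]
    archive@boxes <- B[keep, , drop = FALSE]
    archive@positions <- archive@positions[keep]
  }
  archive@objectives <- rbind(archive@objectives, objectives)
  archive@boxes <- rbind(archive@boxes, box)
  archive@positions <- c(archive@positions, list(position))
  rownames(archive@objectives) <- NULL
  rownames(archive@boxes) <- NULL
  archive
}

#' Write an archive snapshot as JSON lines
#'
#' One record per member: generation, objectives, box index, and a bicluster
#' summary (gene/condition counts) when positions are decodable.
#'
#' @param archive an [EpsArchive-class].
#' @param path output file; opened in append mode.
#' @param generation integer tag stored with each record.
#' @return \code{path}, invisibly.
#' @export
writeArchiveSnapshot <- function(archive, path, generation = NA_integer_) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(archiveSize(archive))) {
    rec <- list(generation = generation,
                objectives = archive@objectives[i, ],
                box_index = archive@boxes[i, ])
    pos <- archive@positions[[i]]
    if (!is.null(pos) && archive@n > 0L) {
      rec$genes <- sum(pos[seq_len(archive@n)])
      rec$conditions <- sum(pos[archive@n + seq_len(archive@m)])
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
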