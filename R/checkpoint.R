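# Checkpoints are a flat named-array container serialized as JSON:
# each entry records its dimensions and values, so files are plain text
# and portable.

.flatten_net <- function(net, prefix) {
  out <- list()
  add <- function(name, x) {
    out[[name]] <<- list(dim = dim(x) %||% length(x), values = as.numeric(x))
  }
  for (nm in c("Wr", "Wh", "Wz", "br", "bh", "bz", "Wbeta", "bbeta")) {
    add(paste0(prefix, ".f.", nm), net$f[[nm]])
    if (!is.null(net$b)) add(paste0(prefix, ".b.", nm), net$b[[nm]])
  }
  add(paste0(prefix, ".proj.W"), net$proj$W)
  add(paste0(prefix, ".proj.b"), net$proj$b)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.unflatten_cell <- function(flat, prefix, h, d) {
  keys <- paste0(prefix, ".", c("Wr", "Wh", "Wz", "br", "bh", "bz", "Wbeta", "bbeta"))
  if (!all(keys %in% names(flat))) {
    return(NULL)
  }
  get <- function(nm) {
    e <- flat[[paste0(prefix, ".", nm)]]
    v <- as.numeric(e$values)
    if (length(e$dim) == 2L) matrix(v, e$dim[1L], e$dim[2L]) else v
  }
  list(
    Wr = get("Wr"), Wh = get("Wh"), Wz = get("Wz"),
    br = get("br"), bh = get("bh"), bz = get("bz"),
    Wbeta = get("Wbeta"), bbeta = get("bbeta"),
    H = as.integer(h), D = as.integer(d)
  )
}

#' Save imputer networks to a text checkpoint
#'
#' Writes all weights as a flat named-array JSON container together
#' with the direction and sizes, so a trained model can be reloaded
#' with [loadImputerNets()].
#'
#' @param nets An [ImputerNets-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveImputerNets <- function(nets, path) {
  payload <- list(
    format = "tbigain-checkpoint-1",
    direction = nets@direction,
    hiddenSize = nets@hiddenSize,
    inputSize = nets@inputSize,
    arrays = c(
      .flatten_net(nets@generator, "generator"),
      .flatten_net(nets@discriminator, "discriminator")
    )
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}

#' Load imputer networks from a checkpoint
#'
#' @param path file written by [saveImputerNets()].
#' @return An [ImputerNets-class].
#' @export
loadImputerNets <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "tbigain-checkpoint-1")) {
    stop("not a tbigain checkpoint: ", path)
  }
  h <- as.integer(payload$hiddenSize)
  d <- as.integer(payload$inputSize)
  flat <- payload$arrays
  read_net <- function(prefix) {
    pe <- flat[[paste0(prefix, ".proj.W")]]
    list(
      f = .unflatten_cell(flat, paste0(prefix, ".f"), h, d),
      b = .unflatten_cell(flat, paste0(prefix, ".b"), h, d),
      proj = list(
        W = matrix(as.numeric(pe$values), pe$dim[1L], pe$dim[2L]),
        b = as.numeric(flat[[paste0(prefix, ".proj.b")]]$values)
      )
    )
  }
  nets <- new("ImputerNets",
    generator = read_net("generator"),
    discriminator = read_net("discriminator"),
    direction = payload$direction,
    hiddenSize = h, inputSize = d
  )
  validObject(nets)
  nets
}
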