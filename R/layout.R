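#' Build a synthetic MEG sensor layout
#'
#' A layout groups channels into co-located *sites*: each site carries two
#' gradiometers and one magnetometer at the same 2-D position, so a layout
#' with `n_sites` sites has `3 * n_sites` channels. Sites are placed
#' quasi-uniformly on a unit disc (sunflower spiral, jittered by `seed`).
#' Each site also gets a spatial *neighbourhood*: itself plus its 3 nearest
#' sites, i.e. 4 sites / 12 channels, the block used by spatiotemporal and
#' spatio-spectral permutation importance.
#'
#' @param n_sites number of sensor sites (>= 1); channels = 3 * n_sites.
#' @param seed integer seed controlling the positional jitter.
#' @return An object of class `meg_layout`: a list with
#'   \describe{
#'     \item{n_sites, n_channels}{counts.}
#'     \item{positions}{`n_sites x 2` matrix of site coordinates.}
#'     \item{channels}{data.frame with `channel`, `site`, `type`
#'       (`"grad"`/`"mag"`).}
#'     \item{site_channels}{list: channel indices (length 3) per site.}
#'     \item{neighbors}{list: site indices of each site's neighbourhood
#'       (itself + up to 3 nearest sites).}
#'   }
#' @examples
#' lay <- make_sensor_layout(10, seed = 1)
#' lengths(lay$neighbors)  # all 4
#' @export
make_sensor_layout <- function(n_sites, seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("`n_sites` must be a single integer >= 1")
  n_sites <- as.integer(n_sites)
  rng <- local_rng(seed)
  # sunflower arrangement: radius ~ sqrt(k), golden-angle azimuth, small jitter
  k <- seq_len(n_sites)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((k - 0.5) / n_sites)
  theta <- k * golden + rng$runif(n_sites, -0.05, 0.05)
  positions <- cbind(x = r * cos(theta), y = r * sin(theta))
  rownames(positions) <- paste0("site", k)

  channels <- data.frame(
    channel = seq_len(3L * n_sites),
    site = rep(k, each = 3L),
    type = rep(c("grad", "grad", "mag"), times = n_sites),
    stringsAsFactors = FALSE
  )
  site_channels <- split(channels$channel, channels$site)
  names(site_channels) <- NULL

  d <- as.matrix(stats::dist(positions))
  neighbors <- lapply(k, function(s) {
    ord <- order(d[s, ], k)          # distance, ties by site index
    ord <- ord[ord != s]
    c(s, utils::head(ord, 3L))
  })

  structure(
    list(n_sites = n_sites, n_channels = 3L * n_sites,
         positions = positions, channels = channels,
         site_channels = site_channels, neighbors = neighbors),
    class = "meg_layout"
  )
}

#' @export
print.meg_layout <- function(x, ...) {
  cat("<meg_layout> ", x$n_sites, " sites / ", x$n_channels,
      " channels (2 grad + 1 mag per site)\n", sep = "")
  invisible(x)
}

#' Channel indices of a site neighbourhood
#'
#' @param layout a [make_sensor_layout()] layout.
#' @param site site index.
#' @return integer vector of channel indices (12 for layouts with >= 4 sites).
#' @keywords internal
neighborhood_channels <- function(layout, site) {
  sites <- layout$neighbors[[site]]
  unlist(layout$site_channels[sites], use.names = FALSE)
}

# Run code with a private RNG stream, leaving the global RNG state untouched.
# Returns a list of draw functions bound to the private stream.
local_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state$seed <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  restore()
  with_stream <- function(expr_fun) {
    old2 <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state$seed, envir = globalenv())
    on.exit({
      state$seed <- get(".Random.seed", globalenv())
      if (is.null(old2)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old2, envir = globalenv())
    })
    expr_fun()
  }
  list(
    runif = function(n, min = 0, max = 1)
      with_stream(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      with_stream(function() stats::rnorm(n, mean, sd)),
    sample = function(x, size = NULL, replace = FALSE)
      with_stream(function() {
        if (is.null(size))
          size <- if (length(x) == 1L && is.numeric(x) && x >= 1) x
            else length(x)
        sample(x, size, replace)
      }),
    eval = function(f) with_stream(f)
  )
}
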