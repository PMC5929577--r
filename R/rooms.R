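# The diabolical rooms problem: a sequence of grid-world rooms, each with
# three doors in the corners. One door (the same corner in every room)
# advances the agent to the next room and pays 1; the other two teleport
# the agent back to the start of room 1 and pay 0. Mappings vary across
# rooms, so exploration costs compound with task depth.

#' Construct a diabolical rooms task
#'
#' Rooms are square grids with doors in the NW, NE and SE corners; the NE
#' door is the advancing (rewarded) door in every room, and the agent
#' starts each room in the SW corner. The paper-style default is six 6x6
#' rooms with three orthogonal mappings in the order
#' phi1 phi1 phi2 phi2 phi3 phi3.
#'
#' @param n_rooms Number of rooms.
#' @param room_size Side length of each (square) room, at least 3 so that
#'   the three corner doors and the start are distinct.
#' @param mapping_order Integer vector of length `n_rooms` giving the
#'   mapping index (into a set of 3 orthogonal mappings) of each room.
#'   Defaults to `rep(1:3, each = n_rooms/3)` style blocks via
#'   [rooms_mapping_order()].
#' @param seed Integer seed (controls the mapping set).
#' @return An object of class `rooms_spec` with fields `n_rooms`, `grid`,
#'   `mappings`, `mapping_order`, `doors` (named integer cells for NW, NE,
#'   SE), `correct_door` (the NE cell), and `start` (SW cell).
#' @export
make_rooms_spec <- function(n_rooms = 6L, room_size = 6L,
                            mapping_order = NULL, seed = 0L) {
  n_rooms <- as.integer(n_rooms)
  room_size <- as.integer(room_size)
  if (room_size < 3L) stop("room too small to place 3 corner doors and a distinct start")
  if (is.null(mapping_order)) mapping_order <- rooms_mapping_order(n_rooms)
  mapping_order <- as.integer(mapping_order)
  stopifnot(length(mapping_order) == n_rooms, all(mapping_order %in% 1:3))
  grid <- grid_spec(room_size, room_size)
  w <- room_size
  doors <- c(NW = xy_to_cell(0L, w - 1L, w),
             NE = xy_to_cell(w - 1L, w - 1L, w),
             SE = xy_to_cell(w - 1L, 0L, w))
  mappings <- make_orthogonal_mappings(3L, seed = seed)
  structure(list(n_rooms = n_rooms, grid = grid, mappings = mappings,
                 mapping_order = mapping_order, doors = doors,
                 correct_door = doors[["NE"]], start = xy_to_cell(0L, 0L, w),
                 seed = as.integer(seed)),
            class = "rooms_spec")
}

#' Block mapping order for rooms tasks
#'
#' Returns the sequence phi1^(k) phi2^(k) phi3^(k) with `k = n_rooms/3`
#' repeats of each of the three mappings (`n_rooms` must be a multiple
#' of 3). For the 6-room default this is phi1 phi1 phi2 phi2 phi3 phi3.
#'
#' @param n_rooms Number of rooms, a multiple of 3.
#' @return Integer vector of mapping indices.
#' @export
rooms_mapping_order <- function(n_rooms) {
  if (n_rooms %% 3L != 0L) stop("n_rooms must be a multiple of 3")
  rep(1:3, each = n_rooms %/% 3L)
}

#' @export
print.rooms_spec <- function(x, ...) {
  cat(sprintf("<rooms_spec: %d rooms of %dx%d, mapping order %s>\n",
              x$n_rooms, x$grid$width, x$grid$height,
              paste0("phi", x$mapping_order, collapse = " ")))
  invisible(x)
}

#' Take one step in the rooms task
#'
#' Movement follows the current room's mapping with wall clamping as in
#' [env_step()]. Entering the correct (NE) door pays 1 and advances to the
#' next room's start (completing the task from the last room); entering
#' either wrong door pays 0 and teleports the agent to room 1's start.
#' All other steps are ordinary navigation with 0 reward.
#'
#' @param spec A `rooms_spec`.
#' @param room Current room index in 1..n_rooms.
#' @param cell Current cell index.
#' @param action Primitive action index in 1..8.
#' @return A list with `cell` (cell entered in the current room, before
#'   any room transition), `movement`, `reward`, `event` (one of "move",
#'   "advance", "reset"), `room` (room index after the step), `loc` (cell
#'   index after any transition) and `task_done`.
#' @export
rooms_step <- function(spec, room, cell, action) {
  if (room < 1L || room > spec$n_rooms) stop("invalid room index")
  if (cell < 1L || cell > spec$grid$n_cells) stop("cell out of bounds")
  mv <- spec$mappings[[spec$mapping_order[room]]][[action]]
  nxt <- unname(spec$grid$succ[cell, mv])
  if (nxt == spec$correct_door) {
    done <- room == spec$n_rooms
    list(cell = nxt, movement = mv, reward = 1L, event = "advance",
         room = if (done) room else room + 1L, loc = spec$start,
         task_done = done)
  } else if (nxt %in% spec$doors) {
    list(cell = nxt, movement = mv, reward = 0L, event = "reset",
         room = 1L, loc = spec$start, task_done = FALSE)
  } else {
    list(cell = nxt, movement = mv, reward = 0L, event = "move",
         room = room, loc = nxt, task_done = FALSE)
  }
}
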