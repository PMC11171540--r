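# --- Pascal-VOC / YOLO annotation conversion --------------------------------

#' Bounding box in Pascal-VOC pixel coordinates
#'
#' Boxes are held internally as 0-based, half-open pixel intervals
#' (`0 <= xmin < xmax <= width`); Pascal-VOC XML's 1-based inclusive corners
#' are converted on read by [read_voc_xml()].
#'
#' @param label class name.
#' @param xmin,ymin,xmax,ymax pixel corners (0-based, half-open).
#' @param width,height image dimensions in pixels.
#' @return a `voc_box`.
#' @export
voc_box <- function(label, xmin, ymin, xmax, ymax, width, height) {
  abort_if(xmin >= xmax || ymin >= ymax,
           sprintf("degenerate box for '%s': [%g,%g)x[%g,%g)",
                   label, xmin, xmax, ymin, ymax),
           class = "savehsi_box_error")
  abort_if(xmin < 0 || ymin < 0 || xmax > width || ymax > height,
           sprintf("box [%g,%g)x[%g,%g) exceeds %gx%g image",
                   xmin, xmax, ymin, ymax, width, height),
           class = "savehsi_box_error")
  structure(list(label = label, xmin = xmin, ymin = ymin, xmax = xmax,
                 ymax = ymax, width = width, height = height),
            class = "voc_box")
}

#' Default detection class map
#'
#' Class indices used for YOLO label files: dysplasia = 0, scc = 1
#' (precancerous and malignant lesion classes). Normal frames carry empty
#' label files by YOLO convention.
#'
#' @return named integer vector.
#' @export
default_class_map <- function() c(dysplasia = 0L, scc = 1L)

#' Convert a VOC box to YOLO normalised coordinates
#'
#' YOLO stores the box centre and size as fractions of the image size:
#' `x_center = (xmin + xmax) / (2 * width)` etc.
#'
#' @param box a [voc_box()].
#' @param class_map named integer vector mapping label to class index.
#' @return a `yolo_box` with `class_index`, `x_center`, `y_center`,
#'   `box_width`, `box_height`.
#' @export
voc_to_yolo <- function(box, class_map = default_class_map()) {
  abort_if(!box$label %in% names(class_map),
           sprintf("unknown label '%s'; known classes: %s", box$label,
                   paste(names(class_map), collapse = ", ")),
           class = "savehsi_label_error")
  structure(list(
    class_index = unname(class_map[[box$label]]),
    x_center = (box$xmin + box$xmax) / (2 * box$width),
    y_center = (box$ymin + box$ymax) / (2 * box$height),
    box_width = (box$xmax - box$xmin) / box$width,
    box_height = (box$ymax - box$ymin) / box$height),
    class = "yolo_box")
}

#' @rdname voc_to_yolo
#' @param yolo a `yolo_box`.
#' @param width,height image dimensions for denormalisation.
#' @return `yolo_to_voc` returns a [voc_box()] with integer corners
#'   (round-trips within 0.5 px).
#' @export
yolo_to_voc <- function(yolo, class_map = default_class_map(),
                        width, height) {
  idx <- match(yolo$class_index, class_map)
  abort_if(is.na(idx), sprintf("class index %d not in class map",
                               yolo$class_index),
           class = "savehsi_label_error")
  voc_box(names(class_map)[idx],
          xmin = round((yolo$x_center - yolo$box_width / 2) * width),
          ymin = round((yolo$y_center - yolo$box_height / 2) * height),
          xmax = round((yolo$x_center + yolo$box_width / 2) * width),
          ymax = round((yolo$y_center + yolo$box_height / 2) * height),
          width = width, height = height)
}

#' Read a Pascal-VOC XML annotation file
#'
#' Parses image size and all `<object>` boxes; VOC's 1-based inclusive
#' corners become 0-based half-open intervals (`xmin - 1`, `xmax`).
#'
#' @param path XML file path.
#' @return list with `filename`, `width`, `height`, and `boxes` (a list of
#'   [voc_box()]).
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- lapply(objs, function(o) {
    get1 <- function(q) xml2::xml_text(xml2::xml_find_first(o, q))
    voc_box(get1("./name"),
            xmin = as.numeric(get1(".//xmin")) - 1,
            ymin = as.numeric(get1(".//ymin")) - 1,
            xmax = as.numeric(get1(".//xmax")),
            ymax = as.numeric(get1(".//ymax")),
            width = width, height = height)
  })
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
       width = width, height = height, boxes = boxes)
}

#' Write YOLO label lines for a set of boxes
#'
#' One object per line: `class x_center y_center width height` with
#' normalised coordinates. An empty box list yields an empty file (the YOLO
#' convention for frames without findings).
#'
#' @param boxes list of [voc_box()].
#' @param path output `.txt` path.
#' @param class_map named integer vector.
#' @return `path` invisibly.
#' @export
write_yolo_txt <- function(boxes, path, class_map = default_class_map()) {
  lines <- vapply(boxes, function(b) {
    y <- voc_to_yolo(b, class_map)
    sprintf("%d %.10f %.10f %.10f %.10f", y$class_index, y$x_center,
            y$y_center, y$box_width, y$box_height)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a directory of VOC XML annotations to YOLO label files
#'
#' @param xml_dir directory containing `.xml` files.
#' @param out_dir output directory for `.txt` files (created if needed).
#' @param class_map named integer vector.
#' @return data.frame summarising files and box counts, invisibly.
#' @export
convert_voc_dir <- function(xml_dir, out_dir, class_map = default_class_map()) {
  files <- list.files(xml_dir, pattern = "\\.xml$", full.names = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_boxes <- vapply(files, function(f) {
    ann <- read_voc_xml(f)
    out <- file.path(out_dir, sub("\\.xml$", ".txt", basename(f)))
    write_yolo_txt(ann$boxes, out, class_map)
    length(ann$boxes)
  }, integer(1))
  invisible(data.frame(xml = files, n_boxes = n_boxes))
}

# --- image resizing ----------------------------------------------------------

#' Resize an image to the model input size
#'
#' `policy = "stretch"` rescales both axes independently to the target;
#' `policy = "letterbox"` preserves aspect ratio and pads symmetrically
#' (pad value 114/255, the YOLO convention). The returned `transform`
#' (scales and offsets) lets annotation boxes be mapped consistently via
#' [transform_box()].
#'
#' @param image H x W x 3 array in \[0, 1\], or a PNG/JPEG path.
#' @param size target `c(height, width)`; default 640 x 640.
#' @param policy `"stretch"` or `"letterbox"`.
#' @return list with `image` (resized array) and `transform`
#'   (`scale_x`, `scale_y`, `pad_x`, `pad_y`).
#' @export
resize_image <- function(image, size = c(640, 640),
                         policy = c("stretch", "letterbox")) {
  policy <- match.arg(policy)
  if (is.character(image)) image <- read_rgb_image(image)
  abort_if(length(dim(image)) != 3 || any(dim(image)[1:2] < 1),
           "non-empty H x W x 3 image required",
           class = "savehsi_format_error")
  h <- dim(image)[1]; w <- dim(image)[2]
  th <- size[1]; tw <- size[2]
  # EBImage works in x (width), y (height) order
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  if (policy == "stretch") {
    res <- EBImage::resize(eb, w = tw, h = th)
    out <- aperm(EBImage::imageData(res), c(2, 1, 3))
    tr <- list(scale_x = tw / w, scale_y = th / h, pad_x = 0, pad_y = 0)
  } else {
    s <- min(tw / w, th / h)
    nw <- round(w * s); nh <- round(h * s)
    res <- aperm(EBImage::imageData(EBImage::resize(eb, w = nw, h = nh)),
                 c(2, 1, 3))
    pad_x <- floor((tw - nw) / 2); pad_y <- floor((th - nh) / 2)
    out <- array(114 / 255, c(th, tw, 3))
    out[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- res
    tr <- list(scale_x = s, scale_y = s, pad_x = pad_x, pad_y = pad_y)
  }
  list(image = out, transform = tr)
}

#' @rdname resize_image
#' @param box a [voc_box()].
#' @param transform the `transform` element returned by `resize_image`.
#' @param size target `c(height, width)` of the resized image.
#' @return `transform_box` returns the box mapped into the resized frame.
#' @export
transform_box <- function(box, transform, size = c(640, 640)) {
  voc_box(box$label,
          xmin = box$xmin * transform$scale_x + transform$pad_x,
          ymin = box$ymin * transform$scale_y + transform$pad_y,
          xmax = box$xmax * transform$scale_x + transform$pad_x,
          ymax = box$ymax * transform$scale_y + transform$pad_y,
          width = size[2], height = size[1])
}

# --- dataset splitting -------------------------------------------------------

#' Split dataset items into train / validation / test partitions
#'
#' Seeded shuffle followed by a contiguous cut. Partition sizes are
#' `floor(n * ratio)` with all remainder items assigned to the last
#' partition, so 2741 items at 70:15:15 give 1918/411/412. With `group_key`
#' set (e.g. patient id), whole groups are assigned together — groups are
#' shuffled and the cut falls on the first group boundary at or past each
#' target size — so no group is ever split across partitions.
#'
#' @param items character/integer vector of item ids.
#' @param ratios three fractions summing to 1 (default 70:15:15).
#' @param seed integer seed for the shuffle.
#' @param group_key optional vector, same length as `items`.
#' @param names partition names.
#' @return a `split_plan`: list with `assignment` (named factor over items),
#'   `ratios`, `seed`, `counts`.
#' @export
split_dataset <- function(items, ratios = c(0.70, 0.15, 0.15), seed = 1,
                          group_key = NULL,
                          names = c("train", "val", "test")) {
  abort_if(length(items) == 0, "no items to split")
  abort_if(length(ratios) != length(names) || any(ratios < 0) ||
             abs(sum(ratios) - 1) > 1e-9,
           "ratios must be non-negative and sum to 1")
  n <- length(items)
  targets <- floor(n * ratios)
  targets[length(targets)] <- n - sum(targets[-length(targets)])
  assignment <- character(n)
  if (is.null(group_key)) {
    ord <- with_seed(seed, sample.int(n))
    bounds <- cumsum(targets)
    part <- rep(names, times = targets)
    assignment[ord] <- part
  } else {
    abort_if(length(group_key) != n, "group_key length must match items")
    abort_if(anyNA(group_key), "group_key must not contain missing values")
    groups <- unique(group_key)
    gord <- with_seed(seed, sample(groups))
    sizes <- vapply(gord, function(g) sum(group_key == g), integer(1))
    starts <- cumsum(sizes) - sizes # 0-based start of each group's item run
    cutpts <- cumsum(targets)[-length(targets)]
    pidx <- vapply(starts, function(s) sum(s >= cutpts) + 1L, integer(1))
    assignment <- names[pidx][match(group_key, gord)]
  }
  assignment <- factor(assignment, levels = names)
  structure(list(assignment = stats::setNames(assignment, items),
                 ratios = ratios, seed = seed,
                 counts = table(assignment)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", paste(sprintf("%s=%d", names(x$counts), x$counts),
                            collapse = " "), "\n")
  invisible(x)
}
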