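{
  "version": "5.0.1",
  "flags": {},
  "imageHeight": 64,
  "imageWidth": 64,
  "imagePath": "synthetic_cell.png",
  "shapes": [
    {
      "label": "cytoplasm",
      "shape_type": "polygon",
      "points": [
        [12.0, 30.0], [16.5, 18.0], [25.0, 11.5], [36.0, 10.0],
        [46.5, 14.0], [52.0, 23.0], [53.0, 34.0], [48.5, 44.0],
        [38.0, 51.0], [26.0, 51.5], [16.0, 45.0], [11.5, 37.0]
      ]
    },
    {
      "label": "nucleus",
      "shape_type": "polygon",
      "points": [
        [22.0, 28.0], [26.0, 21.0], [33.0, 18.5], [40.0, 21.0],
        [43.5, 27.0], [42.0, 34.0], [36.5, 38.5], [29.0, 38.0],
        [23.5, 33.5]
      ]
    }
  ]
}
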