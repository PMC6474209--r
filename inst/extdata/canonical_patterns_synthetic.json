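[
  {
    "label": "F5",
    "channel_pulses": [
      [60, 67, 74, 81, 88, 248, 255, 262, 269],
      [72, 79, 86, 93, 100, 260, 267, 274, 281],
      [84, 91, 98, 105, 112, 272, 279, 286, 293],
      [96, 103, 110, 117, 124, 284, 291, 298, 305]
    ],
    "duration": 340
  },
  {
    "label": "S5",
    "channel_pulses": [
      [60, 83, 106, 129, 152, 175, 198, 221, 244, 267, 290, 313],
      [72, 95, 118, 141, 164, 187, 210, 233, 256, 279, 302],
      [84, 107, 130, 153, 176, 199, 222, 245, 268, 291, 314],
      [96, 119, 142, 165, 188, 211, 234, 257, 280, 303]
    ],
    "duration": 340
  },
  {
    "label": "F10",
    "channel_pulses": [
      [30, 37, 44, 51, 58, 214, 221, 228, 235],
      [42, 49, 56, 63, 70, 226, 233, 240, 247],
      [54, 61, 68, 75, 82, 238, 245, 252, 259],
      [66, 73, 80, 87, 94, 250, 257, 264, 271]
    ],
    "duration": 340
  },
  {
    "label": "S10",
    "channel_pulses": [
      [30, 58, 86, 114, 142, 170, 198, 226, 254, 282, 310],
      [42, 70, 98, 126, 154, 182, 210, 238, 266, 294],
      [54, 82, 110, 138, 166, 194, 222, 250, 278, 306],
      [66, 94, 122, 150, 178, 206, 234, 262, 290, 318]
    ],
    "duration": 340
  },
  {
    "label": "F20",
    "channel_pulses": [
      [15, 22, 29, 36, 43, 197, 204, 211, 218],
      [27, 34, 41, 48, 55, 209, 216, 223, 230],
      [39, 46, 53, 60, 67, 221, 228, 235, 242],
      [51, 58, 65, 72, 79, 233, 240, 247, 254]
    ],
    "duration": 340
  },
  {
    "label": "S20",
    "channel_pulses": [
      [15, 53, 91, 129, 167, 205, 243, 281, 319],
      [27, 65, 103, 141, 179, 217, 255, 293],
      [39, 77, 115, 153, 191, 229, 267, 305],
      [51, 89, 127, 165, 203, 241, 279, 317]
    ],
    "duration": 340
  },
  {
    "label": "Finf",
    "channel_pulses": [
      [5, 12, 19, 26, 33, 199, 206, 213, 220],
      [17, 24, 31, 38, 45, 211, 218, 225, 232],
      [29, 36, 43, 50, 57, 223, 230, 237, 244],
      [41, 48, 55, 62, 69, 235, 242, 249, 256]
    ],
    "duration": 340
  },
  {
    "label": "Sinf",
    "channel_pulses": [
      [5, 21, 37, 53, 69, 85, 101, 117, 133, 149, 165, 181, 197, 213, 229, 245, 261, 277, 293, 309],
      [17, 33, 49, 65, 81, 97, 113, 129, 145, 161, 177, 193, 209, 225, 241, 257, 273, 289, 305],
      [29, 45, 61, 77, 93, 109, 125, 141, 157, 173, 189, 205, 221, 237, 253, 269, 285, 301, 317],
      [41, 57, 73, 89, 105, 121, 137, 153, 169, 185, 201, 217, 233, 249, 265, 281, 297, 313]
    ],
    "duration": 340
  }
]
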