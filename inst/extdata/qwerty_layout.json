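{
  "name": "qwerty-dubeolsik",
  "style": "plain",
  "rows": 3,
  "cols": 10,
  "home": [0, 0],
  "grid": [
    [
      {"kind": "jamo", "taps": ["ㅂ"], "label": "ㅂ"},
      {"kind": "jamo", "taps": ["ㅈ"], "label": "ㅈ"},
      {"kind": "jamo", "taps": ["ㄷ"], "label": "ㄷ"},
      {"kind": "jamo", "taps": ["ㄱ"], "label": "ㄱ"},
      {"kind": "jamo", "taps": ["ㅅ"], "label": "ㅅ"},
      {"kind": "jamo", "taps": ["ㅛ"], "label": "ㅛ"},
      {"kind": "jamo", "taps": ["ㅕ"], "label": "ㅕ"},
      {"kind": "jamo", "taps": ["ㅑ"], "label": "ㅑ"},
      {"kind": "jamo", "taps": ["ㅐ"], "label": "ㅐ"},
      {"kind": "jamo", "taps": ["ㅔ"], "label": "ㅔ"}
    ],
    [
      {"kind": "jamo", "taps": ["ㅁ"], "label": "ㅁ"},
      {"kind": "jamo", "taps": ["ㄴ"], "label": "ㄴ"},
      {"kind": "jamo", "taps": ["ㅇ"], "label": "ㅇ"},
      {"kind": "jamo", "taps": ["ㄹ"], "label": "ㄹ"},
      {"kind": "jamo", "taps": ["ㅎ"], "label": "ㅎ"},
      {"kind": "jamo", "taps": ["ㅗ"], "label": "ㅗ"},
      {"kind": "jamo", "taps": ["ㅓ"], "label": "ㅓ"},
      {"kind": "jamo", "taps": ["ㅏ"], "label": "ㅏ"},
      {"kind": "jamo", "taps": ["ㅣ"], "label": "ㅣ"},
      null
    ],
    [
      {"kind": "jamo", "taps": ["ㅋ"], "label": "ㅋ"},
      {"kind": "jamo", "taps": ["ㅌ"], "label": "ㅌ"},
      {"kind": "jamo", "taps": ["ㅊ"], "label": "ㅊ"},
      {"kind": "jamo", "taps": ["ㅍ"], "label": "ㅍ"},
      {"kind": "jamo", "taps": ["ㅠ"], "label": "ㅠ"},
      {"kind": "jamo", "taps": ["ㅜ"], "label": "ㅜ"},
      {"kind": "jamo", "taps": ["ㅡ"], "label": "ㅡ"},
      {"kind": "function", "action": "SPACE", "label": "SPC"},
      {"kind": "function", "action": "PERIOD", "label": "."},
      {"kind": "function", "action": "ENTER", "label": "ENT"}
    ]
  ]
}
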