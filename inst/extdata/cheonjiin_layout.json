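{
  "name": "cheonjiin",
  "style": "cheonjiin",
  "rows": 4,
  "cols": 4,
  "home": [0, 0],
  "grid": [
    [
      {"kind": "vowel", "taps": ["ㅣ"], "label": "ㅣ"},
      {"kind": "vowel", "taps": ["ㆍ"], "label": "ㆍ"},
      {"kind": "vowel", "taps": ["ㅡ"], "label": "ㅡ"},
      {"kind": "function", "action": "DELETE", "label": "DEL"}
    ],
    [
      {"kind": "consonant", "taps": ["ㄱ", "ㅋ", "ㄲ"], "label": "ㄱㅋ"},
      {"kind": "consonant", "taps": ["ㄴ", "ㄹ"], "label": "ㄴㄹ"},
      {"kind": "consonant", "taps": ["ㄷ", "ㅌ", "ㄸ"], "label": "ㄷㅌ"},
      {"kind": "function", "action": "SPACE", "label": "SPC"}
    ],
    [
      {"kind": "consonant", "taps": ["ㅂ", "ㅍ", "ㅃ"], "label": "ㅂㅍ"},
      {"kind": "consonant", "taps": ["ㅅ", "ㅎ", "ㅆ"], "label": "ㅅㅎ"},
      {"kind": "consonant", "taps": ["ㅈ", "ㅊ", "ㅉ"], "label": "ㅈㅊ"},
      {"kind": "function", "action": "ENTER", "label": "ENT"}
    ],
    [
      null,
      {"kind": "consonant", "taps": ["ㅇ", "ㅁ"], "label": "ㅇㅁ"},
      null,
      {"kind": "function", "action": "PERIOD", "label": "."}
    ]
  ]
}
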