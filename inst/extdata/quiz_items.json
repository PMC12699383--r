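{
  "_comment": "Synthetic, non-canonical item bank: nine behavioural screening items covering themes commonly probed in dyslexia symptom checklists. Editable; replace with a validated instrument for clinical use. Options are ordered by increasing concern and scored 0-3.",
  "id": ["Q1", "Q2", "Q3", "Q4", "Q5", "Q6", "Q7", "Q8", "Q9"],
  "text": [
    "How often does the child confuse visually similar letters (such as b and d, or p and q) when reading or writing?",
    "How often does the child struggle to recognise or produce rhyming words?",
    "How consistently does the child spell the same word differently within one piece of writing?",
    "How often does the child lose their place, skip lines, or re-read lines while reading aloud?",
    "How often does the child read noticeably more slowly than classmates of the same age?",
    "How often does the child avoid reading aloud or become frustrated when asked to read?",
    "How often does the child mix up the order of letters or syllables when writing words?",
    "How often does the child have difficulty remembering sequences such as days of the week or the alphabet?",
    "How often does the child struggle to sound out unfamiliar words?"
  ],
  "options": [
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"],
    ["Never", "Occasionally", "Often", "Almost always"]
  ]
}
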