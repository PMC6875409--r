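cwlVersion: v1.0
class: CommandLineTool
id: complex_tool
doc: Tool with a record-typed input (maps to the text-input fallback)
baseCommand: complex
inputs:
  settings:
    type:
      type: record
      fields: []
    doc: Nested settings record
  plain:
    type: string
outputs: []
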