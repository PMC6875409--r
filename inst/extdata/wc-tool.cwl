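cwlVersion: v1.0
class: CommandLineTool
id: wc_tool
doc: Count bytes in a file
baseCommand: wc
inputs:
  infile:
    type: File
    doc: File to count
    inputBinding:
      prefix: -c
outputs: []
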