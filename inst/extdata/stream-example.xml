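<?xml version="1.0" encoding="UTF-8"?>
<template id="stream_example" title="Stream an input file" description="Pipe a file to a network listener, or append it to a local file.">
<window>
<label>Select the input file to stream</label>
<filedialog id="input" label="Input file" mode="open" hint="File whose contents will be piped"/>
<group id="os" title="Stream over the network" checkable="true">
<filedialog id="outfile" label="Output file" mode="save" default="output.txt" hint="Local file to append to when not streaming"/>
</group>
<action label="Run"/>
<streambox/>
</window>
<execution>
<if id="output" probe="${os}" equals="TRUE"><then>netcat 192.168.1.100 55025</then><else>tee -a ${outfile}</else></if>
<execute program="sh"><param>-c</param><param>"cat ${input} | ${output}"</param></execute>
</execution>
</template>
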