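<?xml version="1.0" encoding="UTF-8"?>
<template id="minimal" title="Show a file">
<window>
<filedialog id="input" label="Input file"/>
<action label="Run"/>
<streambox/>
</window>
<execution>
<execute program="cat"><param>${input}</param></execute>
</execution>
</template>
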