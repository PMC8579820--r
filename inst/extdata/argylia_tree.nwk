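(((uspallatensis:9.76,bustillosii:9.76):18.28,(tomentosa:19.25,(bifrons:15.4,(glutinosa:11.55,(geranioides:7.7,(checoensis:3.85,farnesiana:3.85):3.85):3.85):3.85):3.85):8.79):10.17,(robusta:25.77,(potentillifolia:16.33,(radiata:10.886667,(adscendens_adscendens:5.443333,adscendens_viridis:5.443333):5.443334):5.443333):9.44):12.44);
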