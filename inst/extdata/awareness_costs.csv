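activity,resource,amount
Jingle production in 7 languages,Audio,531.96
Jingle production in 7 languages,Video,2127.82
Airing of jingle in Adamawa,Radio stations,82073.12
Airing of jingle in Adamawa,Television stations,20974.24
Airing of jingle in Bauchi,Radio stations,61554.84
Airing of jingle in Bauchi,Television stations,20974.24
Airing of jingle in Borno,Radio stations,61554.84
Airing of jingle in Borno,Television stations,20974.24
Airing of jingle in Gombe,Radio stations,61554.84
Airing of jingle in Gombe,Television stations,20974.24
Airing of jingle in Taraba,Radio stations,41036.56
Airing of jingle in Taraba,Television stations,41948.48
Airing of jingle in Yobe,Radio stations,41036.56
Airing of jingle in Yobe,Television stations,41948.48
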