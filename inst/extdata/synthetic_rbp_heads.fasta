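>g01A_m01 synthetic group G01 subgroup G01A
TNPTNKCPSQCNQAMAKQTSNTMYYLEHYSEDCTTEAGYWSPSMCTWNFDYDAMWSTTYQ
SEQWAKYSVMCWNICKSPGSTRSMHDEHMQMKRCILDCTQCMACDPFFTT
>g01A_m02 synthetic group G01 subgroup G01A
TNPTNKCPSQCNQAMAKDTSQTMYYLEHYSEDCTTEAGYWSPSMCTWVFDYDAMWSTQHQ
SEQWAKYSVMCWNICKSPGSTESPHDEHMQMKRCILWCTQCMACDPKFTT
>g01B_m01 synthetic group G01 subgroup G01B
CFFLPKCMRQNGVVMDKQKSYYMCYREHRSYDCTNKWGHKRPSDCTWNDSGDAMWKDYYE
SKQTIKYSPQCWNTCKSYGETWSPHDEHMQMKACILWCTQCMACDPYHCT
>g01B_m02 synthetic group G01 subgroup G01B
CFFLPKTMRQNNVVMDKQKSYYMCYREHRSYDCTNDWGHKRYSHCTWNDSGDAMWCDMYE
SEQTIKYSPQCWNTCKSYGETWSPHDEHMQMKACILWCTQCMACDPYHRT
>g02_m01 synthetic group G02
RNKEHGSKTIVETVMAKQYTEQNCAADNHGLYDHFNWWWPILQTVPMLFSHKMSMCRLDW
TIVAENENIICGIFWQFRMHIIQCHLLADAAWEMDRPHYHWQPLAFDLFT
>g02_m02 synthetic group G02
RNKEHHSKTIVETVMAKQYTEQNCAADNHGLYSHFNTKLPILQTVPMLFSHKMSMCRLIW
TIVAENDNIKRGIFWQFRMHIIQCHLLADAAWEMDRPHYHNQPLAKDLFT
>g02_m03 synthetic group G02
RAKEHGSKTNVETVMAKTYTEQNCAADNHGLYDHFNTWWPIKQTVPMLFSHKMSMCRLDW
TIVAENDNIKCGIFWQFRMHIIQCHLLADAAWEMDRPHYHWQPLAFDLLT
>g02_m04 synthetic group G02
RNKEHGSKTIVETVMAKQYTEQNCAADNHGLYDHFNTWWPILQTVPMLFSHKMSMCFLDW
TIVAANDNIKCGIFWQFCNHIIQCHLLADAAWIMDRPHNHWQPLAFDLFT
>g03_m01 synthetic group G03
IPCVVTCHCINYSSEEYVNRVAWKCLYWFYLGTCQFTWLGSWFSPCEWSLPPRDVHTGWE
YLGQDVATKRKHAIGMAHVHYKVHVICQPQSWIKCYSGALLGGFLHQMNI
>g03_m02 synthetic group G03
IPCVVTCHCIIYSGEEYVNFVAWKCLYWFYLGTCQFTWLGMWFSPCPWSLPPRDVHTGWE
YLGQDVATKRKHDISMAFVHYKVDAICQPQSWIKCHSYALLGGFLHQMNI
>g03_m03 synthetic group G03
IPCVPTCHCINYSSEAYVNRVAWKCLYWFYLGTCQSTWLGSWFSPCPWSLPPRDVHTGCE
YLGQDVATKRKHAIGMAFVHYWVHAICQPQSWINCYSYALLGGFLHQMNI
>g03_m04 synthetic group G03
IPCVVTCHCINESSEEYVNRVAQKCLYWFYLGTCQFTWLGSWFSPCPWSLPPRDVHTGWE
YLGQDVATKRKSAIGYAFVHYKKHAICQPQSWIKCYSRALLGGFLHQMNY
>singleton_01 synthetic ungrouped
MKYNVWLAMMDCGMIRCQPVKELMSPDYYMEPALQVKVQNSITWKPAEYAMAIGRTQGIT
FARIEWSCARTYDRFESYDTPQIPQEIEFEPDFKKEVETMTPSRNLCYAY
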