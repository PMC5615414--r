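file	md5
annotations.tsv	56c0ec1a6ed8591412ac6d30aaa03402
corpus.jsonl	24d38852f1db4531866e4f6be7536e16
disease_groups.tsv	e4e72938a70917276564b03b5a51f5b4
go.obo	7959a3a505f3fd3f69c92fab19d4f7f4
ground_truth.json	c2309ec9a4e3a0e9c793d0ae07301443
mirna_lexicon.tsv	5ff27240a2732788d9618e49388b15bd
regin_MicroCosmSyn.tsv	b579dfedd0b55cbd4460a7f0716fa5d3
regin_MicroCosmSyn.xgmml	fe6331bb907901784e9b6de1f3b5b4af
regin_TargetScanSyn.tsv	03c6c29dede353b187e8819d3c1e0a4f
regin_TargetScanSyn.xgmml	b2d3fd119439306f33f54fba6b9bd6a9
regin_miRTarBaseSyn.tsv	a8f4ec22a98c4bd18cee9b28e35768f6
regin_miRTarBaseSyn.xgmml	985594ad8585485bedc6052b19968bbf
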