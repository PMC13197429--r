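根据癫痫发作症状描述（发作症状学），估计癫痫起源区位于以下七个脑区中每一个的可能性：{regions}。请仅以 JSON 字典作答，其中这七个脑区名称为键，值为以百分比表示的可能性。
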